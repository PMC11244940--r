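test_that("total current is the double sum over synapses with no cross-talk", {
  n <- random_neuron(2, 2, form = "sigmoid", seed = 1)
  n$a[] <- 0
  expect_equal(total_current(n, c(0.3, 0.8)), 0)
  n1 <- random_neuron(1, 1, form = "sigmoid", seed = 2)
  expect_equal(total_current(n1, 0.4),
               sigmoid_transmission(0.4, n1$a[1, 1], n1$s[1, 1], n1$t[1, 1]))
  # hand sum: four identical synapses at their threshold give 4 * a^2/2 = 2
  n2 <- random_neuron(2, 2, form = "sigmoid", seed = 3)
  n2$a[] <- 1; n2$s[] <- 4; n2$t[] <- 0.5
  expect_equal(total_current(n2, c(0.5, 0.5)), 2)
  expect_error(total_current(n2, c(0.5, 0.5, 0.5)), "axons")
})

test_that("prediction thresholds the current with sign(0) = -1", {
  n <- random_neuron(1, 1, form = "sigmoid", seed = 4)
  n$a[] <- 1; n$s[] <- 4; n$t[] <- 0.5
  n$theta <- total_current(n, 0.5)  # z - theta == 0 exactly
  expect_equal(predict(n, 0.5), -1)
  n$theta <- n$theta - 5
  expect_equal(predict(n, 0.5), 1)
  n$theta <- n$theta + 10
  expect_equal(predict(n, 0.5), -1)
})

test_that("hinge loss and the margin-violation set follow the strict rule", {
  n <- random_neuron(2, 2, seed = 5)
  ps <- random_patterns(6, 2, seed = 5)
  z <- total_current(n, ps$x)
  m <- (z - n$theta) * ps$y
  expect_equal(hinge_loss(n, ps, margin = 0.1), sum(pmax(0, 0.1 - m)))
  expect_identical(margin_violations(n, ps, margin = 0.1), which(0.1 - m > 0))
  # a pattern at margin exactly epsilon is excluded (strict inequality)
  flat <- random_neuron(1, 1, seed = 55)
  flat$a[] <- 0; flat$theta <- -0.1          # every margin is exactly 0.1 for y = +1
  allpos <- new_pattern_set_for_test(rbind(0.2, 0.7), c(1, 1))
  expect_length(margin_violations(flat, allpos, margin = 0.1), 0)
  expect_length(margin_violations(flat, allpos, margin = 0.1 + 1e-9), 2)
  # loss is zero iff all margins >= epsilon
  big <- random_neuron(1, 1, seed = 6)
  big$a[] <- 10; big$s[] <- 50; big$t[] <- 0.5; big$theta <- 0
  sep <- pattern_fixture("sep2")
  expect_equal(hinge_loss(big, sep, margin = 0.1), 0)
})

test_that("a gradient step with an empty violation set changes nothing", {
  big <- random_neuron(1, 1, seed = 7)
  big$a[] <- 10; big$s[] <- 50; big$t[] <- 0.5; big$theta <- 0
  sep <- pattern_fixture("sep2")
  stepped <- gradient_step(big, sep, control = restricted_control())
  expect_equal(stepped$a, big$a)
  expect_equal(stepped$theta, big$theta)
  expect_identical(attr(stepped, "n_violations"), 0L)
})

test_that("the somatic threshold update is the summed label rule", {
  # two +1 patterns both violating: theta decreases by exactly 2 * eta_theta
  n <- random_neuron(1, 1, seed = 8)
  n$a[] <- 0; n$theta <- 0.05  # zero current; both +1 patterns violate
  ps <- new_pattern_set_for_test(rbind(0.2, 0.8), c(1, 1))
  ctrl <- restricted_control(optimizer = "gd", eta_theta = 0.01)
  stepped <- gradient_step(n, ps, control = ctrl)
  expect_equal(stepped$theta, n$theta - 2 * 0.01)
})

test_that("analytic updates equal minus the finite-difference hinge gradient", {
  worst <- 0
  n_checked <- 0
  for (rep in 1:60) for (form in c("tanh", "sigmoid")) {
    n <- random_neuron(2, 2, form = form, seed = 100 + rep)
    ps <- random_patterns(5, 2, seed = 200 + rep)
    m <- (total_current(n, ps$x) - n$theta) * ps$y
    if (any(abs(0.1 - m) < 1e-4)) next  # skip hinge nondifferentiability
    eta <- 1e-7
    st <- gradient_step(n, ps, control = restricted_control(
      optimizer = "gd", eta_a = eta, eta_s = eta, eta_t = eta, eta_theta = eta))
    fd <- oracle_hinge_gradient(n, ps, margin = 0.1)
    for (fld in c("a", "s", "t")) {
      upd <- (st[[fld]] - n[[fld]]) / eta
      ref <- -fd[[fld]]
      sel <- abs(ref) > 1e-4
      if (any(sel)) {
        worst <- max(worst, abs(upd[sel] - ref[sel]) / abs(ref[sel]))
        n_checked <- n_checked + sum(sel)
      }
    }
    updt <- (st$theta - n$theta) / eta
    if (abs(fd$theta) > 1e-4) {
      worst <- max(worst, abs(updt + fd$theta) / abs(fd$theta))
      n_checked <- n_checked + 1
    }
  }
  expect_gt(n_checked, 100)
  expect_lt(worst, 1e-4)
})

test_that("hinge loss is non-increasing under small fixed-rate steps", {
  ok <- 0; tot <- 0
  for (rep in 1:20) {
    n <- random_neuron(3, 2, seed = 300 + rep)
    ps <- random_patterns(10, 3, seed = 400 + rep)
    ctrl <- restricted_control(optimizer = "gd", eta_a = 1e-4, eta_s = 1e-4,
                               eta_t = 1e-4, eta_theta = 1e-4)
    losses <- numeric(11)
    losses[1] <- hinge_loss(n, ps, margin = 0.1)
    for (k in 1:10) {
      n <- gradient_step(n, ps, control = ctrl)
      losses[k + 1] <- hinge_loss(n, ps, margin = 0.1)
    }
    tot <- tot + 1
    if (all(diff(losses) <= 1e-10)) ok <- ok + 1
  }
  expect_gte(ok / tot, 0.95)
})

test_that("per-axon aggregate functions stay nondecreasing through training", {
  ps <- random_patterns(30, 3, seed = 9)
  fit <- restricted_neuron(ps, M = 2,
                           control = restricted_control(max_epochs = 2000, seed = 3))
  grid <- seq(0, 1, length.out = 101)
  for (i in 1:3)
    expect_true(all(diff(aggregate_transmission(fit, i, grid)) >= -1e-12))
  expect_true(all(fit$s >= 0))
})

test_that("resurrection floors dead synapses and redraws their thresholds", {
  n <- random_neuron(2, 2, seed = 10)
  n$a[] <- c(1, 1e-3, 1, 1)   # one dead synapse (a^2 = 1e-6)
  old_t <- n$t
  r <- resurrect_synapses(n, floor = 0.01, seed = 5)
  expect_equal(r$n_resurrected, 1)
  expect_equal(r$neuron$a[2]^2, 0.01)
  expect_true(r$neuron$t[2] >= 0 && r$neuron$t[2] <= 1)
  expect_equal(r$neuron$t[-2], old_t[-2])   # live synapses untouched
  expect_equal(r$neuron$s, n$s)             # slopes untouched
  # deterministic under a fixed seed
  r2 <- resurrect_synapses(n, floor = 0.01, seed = 5)
  expect_identical(r$neuron, r2$neuron)
  # nothing below the floor: no-op
  ok <- random_neuron(2, 2, seed = 11); ok$a[] <- 1
  r3 <- resurrect_synapses(ok, floor = 0.01, seed = 1)
  expect_equal(r3$n_resurrected, 0)
  expect_identical(r3$neuron, ok)
})

test_that("training solves the canonical small tasks", {
  sep <- pattern_fixture("sep2")
  f1 <- restricted_neuron(sep, M = 1,
                          control = restricted_control(max_epochs = 5000, seed = 1))
  expect_true(f1$fit$converged)
  expect_identical(predict(f1, sep$x), sep$y)
  xf <- pattern_fixture("xor4")
  solved <- FALSE
  for (s in 1:5) {
    f <- restricted_neuron(xf, M = 2,
                           control = restricted_control(max_epochs = 10000, seed = s))
    if (f$fit$converged) { solved <- TRUE; break }
  }
  expect_true(solved)
})

test_that("an empty pattern set is an immediate success", {
  empty <- new_pattern_set_for_test(matrix(numeric(0), 0, 2), numeric(0))
  f <- restricted_neuron(empty, M = 2,
                         control = restricted_control(max_epochs = 10, seed = 1))
  expect_true(f$fit$converged)
  expect_identical(f$fit$epochs, 0L)
})

test_that("training is reproducible from its seed", {
  ps <- random_patterns(20, 4, seed = 21)
  ctrl <- restricted_control(max_epochs = 500, seed = 77)
  f1 <- restricted_neuron(ps, M = 2, control = ctrl)
  f2 <- restricted_neuron(ps, M = 2, control = ctrl)
  expect_identical(f1$a, f2$a)
  expect_identical(f1$fit, f2$fit)
})
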