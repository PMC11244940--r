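test_that("envelope solutions match hand-derived closed cases", {
  expect_equal(envelope_solve(c(-1, 1), c(1, 1), 0.5), c(0, 1))
  expect_equal(envelope_solve(c(1, -1, 1), c(1, 1, 1), 0.5), c(0, 0, 1))
  expect_equal(envelope_solve(rep(-1, 6), runif(6) + 0.5, 0.5), rep(0, 6))
  expect_identical(envelope_solve(numeric(0), numeric(0), 1), numeric(0))
  expect_error(envelope_solve(c(1, -1), c(1, 1), -1), "positive")
  expect_error(envelope_solve(c(1, -1), c(1), 0.5), "lengths differ")
})

test_that("the envelope construction equals the brute-force optimum", {
  set.seed(42)
  for (rep in 1:200) {
    P <- sample(2:12, 1)
    y <- sample(c(-1, 1), P, replace = TRUE)
    w <- sample(1:5, P, replace = TRUE) + runif(P) * 0.5
    lam <- runif(1, 0.05, 2)
    got <- envelope_solve(y, w, lam)
    ref <- oracle_staircase(y, w, lam)
    expect_equal(got, ref, tolerance = 1e-6)
    # valid staircase: nondecreasing, nonnegative, pinned first value
    expect_equal(got[1], 0)
    expect_true(all(diff(got) >= -1e-12))
  }
})

test_that("the envelope equals clipped isotonic regression of y w / (2 lambda)", {
  set.seed(7)
  for (rep in 1:50) {
    P <- sample(2:40, 1)
    y <- sample(c(-1, 1), P, replace = TRUE)
    w <- 1 + rpois(P, 2)
    lam <- runif(1, 0.05, 2)
    expect_equal(envelope_solve(y, w, lam), oracle_isotonic(y, w, lam),
                 tolerance = 1e-10)
  }
})

test_that("the solution is invariant under joint scaling of weights and lambda", {
  set.seed(8)
  y <- sample(c(-1, 1), 15, replace = TRUE)
  w <- 1 + rpois(15, 3)
  for (cc in c(0.1, 3, 40))
    expect_equal(envelope_solve(y, cc * w, cc * 0.3), envelope_solve(y, w, 0.3),
                 tolerance = 1e-12)
})

test_that("stationarity holds on every active step", {
  set.seed(9)
  for (rep in 1:40) {
    P <- sample(3:30, 1)
    y <- sample(c(-1, 1), P, replace = TRUE)
    w <- 1 + rpois(P, 2)
    lam <- runif(1, 0.1, 1)
    I <- envelope_solve(y, w, lam)
    steps <- diff(I)
    for (b in which(steps > 1e-10))
      expect_lt(abs(sum(y[(b + 1):P] * w[(b + 1):P] - 2 * lam * I[(b + 1):P])),
                1e-8)
  }
})

test_that("staircase axons evaluate as right-continuous step functions", {
  ax <- list(knots = c(0.2, 0.5, 0.9), values = c(0, 1, 1))
  expect_equal(evaluate_axon(ax, 0.5), 1)   # at a knot
  expect_equal(evaluate_axon(ax, 0.1), 0)   # below all knots
  expect_equal(evaluate_axon(ax, 0.7), 1)   # between knots: value to the left
  expect_equal(evaluate_axon(ax, 0.95), 1)  # above all knots: last value
  expect_equal(evaluate_axon(ax, c(0.2, 0.49)), c(0, 0))
})

test_that("the reweighting loop solves small tasks and degenerate cases", {
  one <- new_pattern_set_for_test(matrix(0.5, 1, 1), 1)
  f1 <- unrestricted_neuron(one)
  expect_true(f1$fit$converged)
  expect_lte(f1$fit$iterations, 2)
  expect_equal(predict(f1, one$x), 1)

  allneg <- new_pattern_set_for_test(matrix(runif(8), 4, 2), rep(-1, 4))
  f2 <- unrestricted_neuron(allneg)
  expect_true(f2$fit$converged)
  expect_identical(f2$fit$iterations, 1L)
  expect_true(all(vapply(f2$axons, function(a) all(a$values == 0), logical(1))))
  expect_identical(predict(f2, allneg$x), rep(-1, 4))

  xf <- pattern_fixture("xor4")
  f3 <- unrestricted_neuron(xf)
  expect_true(f3$fit$converged)
  expect_lte(f3$fit$iterations, 50)
  expect_identical(predict(f3, xf$x), xf$y)
})

test_that("importance weights stay at least one and count misclassifications", {
  ps <- random_patterns(40, 2, seed = 13)   # hard for N = 2: needs reweighting
  f <- unrestricted_neuron(ps, control = unrestricted_control(max_iter = 30))
  expect_true(all(f$weights >= 1))
  expect_true(all(f$weights == round(f$weights)))
  expect_gte(sum(f$weights), 40)
})

test_that("tied inputs are merged into shared knots", {
  x <- cbind(c(0.3, 0.3, 0.7, 0.7), c(0.2, 0.8, 0.4, 0.9))
  ps <- new_pattern_set_for_test(x, c(-1, -1, 1, 1))
  f <- unrestricted_neuron(ps)
  expect_identical(f$axons[[1]]$knots, c(0.3, 0.7))
  expect_length(f$axons[[2]]$knots, 4L)
  expect_true(f$fit$converged)
})

test_that("effective synapses are counted against the neuron-wide maximum step", {
  skel <- function(axsteps) {
    axons <- lapply(axsteps, function(st)
      list(knots = seq_along(c(0, st)) / 10, values = cumsum(c(0, st)),
           steps = st))
    structure(list(N = length(axons), P = 3, axons = axons, theta = 0),
              class = "unrestricted_neuron")
  }
  n <- skel(list(c(0.5, 0.0004, 0.3), c(0.001, 0.002)))
  # neuron-wide max step 0.5, threshold 0.0005, strict ">"
  expect_identical(effective_synapses(n), c(2L, 2L))
  n2 <- skel(list(c(0, 0), c(0, 0)))
  expect_identical(effective_synapses(n2), c(0L, 0L))
  # a lone positive step is its own neuron-wide maximum and clears the
  # max/1000 threshold regardless of its absolute size
  n3 <- skel(list(1e-9))
  expect_identical(effective_synapses(n3), 1L)
})

test_that("trained staircases are monotone and the model fits its training data", {
  ps <- random_patterns(30, 10, seed = 14)
  f <- unrestricted_neuron(ps)
  expect_true(f$fit$converged)
  for (a in f$axons) {
    expect_true(all(diff(a$values) >= -1e-12))
    expect_equal(a$values[1], 0)
    expect_equal(a$steps, diff(a$values))
  }
  expect_identical(predict(f, ps), ps$y)
})
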