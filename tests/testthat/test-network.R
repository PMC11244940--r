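test_that("parameter accounting matches the closed formulas", {
  expect_identical(parameter_count(network_spec(784, 20, 10, M = 3)), 17510L)
  expect_identical(parameter_count(network_spec(784, 22, 10, M = 0)), 17500L)
  expect_identical(parameter_count(network_spec(1, 1, 1, M = 1)), 6L)
  # normalization parameters are reported separately
  expect_identical(parameter_count(network_spec(784, 20, 10, M = 3),
                                   include_norm = TRUE), 17510L + 40L)
})

test_that("the formula agrees with the parameters actually allocated", {
  for (spec in list(network_spec(16, 7, 3, M = 2), network_spec(16, 8, 3, M = 0))) {
    net <- init_network(spec, seed = 1)
    counted <- sum(vapply(net$params[c("W1", "b1", "b_out", "A", "S", "T", "W2")],
                          function(p) if (is.null(p)) 0L else length(p), integer(1)))
    expect_identical(counted, as.integer(parameter_count(spec)))
    bn <- length(net$params$gamma) + length(net$params$beta)
    expect_identical(counted + bn, as.integer(parameter_count(spec, include_norm = TRUE)))
  }
})

test_that("zero-amplitude parallel synapses leave only the output biases", {
  spec <- network_spec(4, 3, 2, M = 2)
  net <- init_network(spec, seed = 2)
  net$params$A[] <- 0
  net$params$b_out <- c(0.3, -0.2)
  Z <- predict(net, matrix(runif(20), 5, 4), type = "logit")
  expect_equal(Z, matrix(rep(c(0.3, -0.2), each = 5), 5, 2))
})

test_that("analytic network gradients match finite differences", {
  for (M in c(2, 0)) {
    spec <- network_spec(5, 4, 3, M = M)
    net <- init_network(spec, seed = 3)
    set.seed(4)
    X <- matrix(runif(40), 8, 5)
    y <- sample(1:3, 8, replace = TRUE)
    loss <- function(net) {
      fw <- parsyn:::network_forward(net, X, training = TRUE)
      p <- exp(fw$Z - apply(fw$Z, 1, max)); p <- p / rowSums(p)
      -mean(log(p[cbind(seq_along(y), y)]))
    }
    g <- parsyn:::network_gradients(net, X, y)$grads
    h <- 1e-5
    for (nm in names(g)) {
      idx <- seq_len(min(6, length(net$params[[nm]])))
      for (k in idx) {
        up <- net; up$params[[nm]][k] <- up$params[[nm]][k] + h
        dn <- net; dn$params[[nm]][k] <- dn$params[[nm]][k] - h
        fd <- (loss(up) - loss(dn)) / (2 * h)
        expect_equal(g[[nm]][k], fd, tolerance = 1e-4,
                     label = sprintf("grad %s[%d] (M=%d)", nm, k, M))
      }
    }
  }
})

test_that("training the tiny image task reaches high held-out accuracy", {
  train <- synthetic_digits(200, d_side = 4, seed = 1)
  test <- synthetic_digits(100, d_side = 4, seed = 2)
  spec <- network_spec(16, 6, 2, M = 3)
  net <- train_network(spec, train$x, train$y, test$x, test$y,
                       epochs = 50, batch_size = 32, seed = 5)
  expect_gt(net$accuracy[length(net$accuracy)], 0.9)
  # fixed seed reproduces the whole trace
  net2 <- train_network(spec, train$x, train$y, test$x, test$y,
                        epochs = 5, batch_size = 32, seed = 5)
  net3 <- train_network(spec, train$x, train$y, test$x, test$y,
                        epochs = 5, batch_size = 32, seed = 5)
  expect_identical(net2$accuracy, net3$accuracy)
})

test_that("monotone constraints hold after training", {
  train <- synthetic_digits(120, d_side = 3, seed = 7)
  # parallel network: per-pair aggregates nondecreasing on a grid
  netp <- train_network(network_spec(9, 4, 2, M = 2), train$x, train$y,
                        epochs = 8, batch_size = 32, seed = 8)
  expect_true(all(netp$params$S >= 0))
  grid <- seq(-2, 4, length.out = 101)
  p <- netp$params
  for (hh in 1:4) for (kk in 1:2) {
    agg <- rowSums(sapply(1:2, function(j)
      p$A[hh, kk, j]^2 * stats::plogis(p$S[hh, kk, j] * (grid - p$T[hh, kk, j]))))
    expect_true(all(diff(agg) >= -1e-12))
  }
  # linear comparison network: nonnegative hidden-to-output weights
  netl <- train_network(network_spec(9, 5, 2, M = 0), train$x, train$y,
                        epochs = 8, batch_size = 32, seed = 9)
  expect_true(all(netl$params$W2 >= 0))
})

test_that("an untrained network predicts at chance", {
  spec <- network_spec(16, 6, 2, M = 3)
  net <- init_network(spec, seed = 11)
  net$run_mean <- rep(0, 6); net$run_var <- rep(1, 6)
  test <- synthetic_digits(400, d_side = 4, seed = 12)
  acc <- mean(predict(net, test$x) == test$y)
  expect_lt(abs(acc - 0.5), 3 * sqrt(0.25 / 400) + 0.15)
})
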