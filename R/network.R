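#' Specify a two-layer network with parallel hidden-to-output synapses
#'
#' The architecture used to test generalization: a fully connected network
#' with linear input-to-hidden synapses, batch normalization of the hidden
#' pre-activations, a Softplus hidden nonlinearity, and hidden-to-output
#' connections made of `M` sigmoidal parallel synapses per neuron pair (each
#' pair's aggregate transmission function is nondecreasing). With `M = 0` the
#' hidden-to-output synapses are single linear weights constrained to be
#' nonnegative — the equal-parameter comparison network.
#'
#' @param d_in input dimension (default 784, for 28 x 28 images).
#' @param d_hidden hidden-layer width.
#' @param d_out number of output classes (default 10).
#' @param M parallel synapses per hidden-to-output pair; `0` for the linear
#'   comparison network.
#' @return An object of class `network_spec`.
#' @examples
#' parameter_count(network_spec(784, 20, 10, M = 3))   # 17510
#' parameter_count(network_spec(784, 22, 10, M = 0))   # 17500
#' @export
network_spec <- function(d_in = 784, d_hidden, d_out = 10, M = 3) {
  structure(list(d_in = check_count(d_in, "d_in"),
                 d_hidden = check_count(d_hidden, "d_hidden"),
                 d_out = check_count(d_out, "d_out"),
                 M = as.integer(M)),
            class = "network_spec")
}

#' @export
print.network_spec <- function(x, ...) {
  cat(sprintf("Two-layer network: %d -> %d -> %d, hidden-to-output via %s\n",
              x$d_in, x$d_hidden, x$d_out,
              if (x$M >= 1) sprintf("%d parallel synapses per pair", x$M)
              else "single nonnegative linear weights"))
  cat(sprintf("  %d learnable parameters (+%d batch-normalization parameters)\n",
              parameter_count(x), 2L * x$d_hidden))
  invisible(x)
}

#' Learnable parameter count of a network specification
#'
#' For the parallel-synapse network the count is
#' `(d_in + 1) d_hidden + (3 M d_hidden + 1) d_out` — each hidden-to-output
#' pair contributes `3 M` parameters (amplitude root, slope, threshold per
#' synapse) — and for the linear comparison network
#' `(d_in + 1) d_hidden + (d_hidden + 1) d_out`. Bias terms of the hidden and
#' output neurons are included. The scale and shift parameters of the batch
#' normalization are conventionally excluded from this count; request them
#' with `include_norm = TRUE`.
#'
#' @param spec a [network_spec()].
#' @param include_norm also count the `2 d_hidden` batch-normalization
#'   parameters.
#' @return Integer parameter count.
#' @export
parameter_count <- function(spec, include_norm = FALSE) {
  stopifnot(inherits(spec, "network_spec"))
  hidden <- (spec$d_in + 1) * spec$d_hidden
  out <- if (spec$M >= 1) (3 * spec$M * spec$d_hidden + 1) * spec$d_out
         else (spec$d_hidden + 1) * spec$d_out
  as.integer(hidden + out + if (include_norm) 2L * spec$d_hidden else 0L)
}

softplus <- function(x) ifelse(x > 30, x, log1p(exp(pmin(x, 30))))

#' Initialise network parameters
#'
#' @param spec a [network_spec()].
#' @param seed integer seed.
#' @return A list of parameter arrays (class `parallel_net`, untrained).
#' @export
init_network <- function(spec, seed = 1L) {
  local_rng(seed, {
    H <- spec$d_hidden; K <- spec$d_out; M <- spec$M
    p <- list(W1 = matrix(stats::rnorm(spec$d_in * H, 0, 1 / sqrt(spec$d_in)),
                          spec$d_in, H),
              b1 = numeric(H),
              gamma = rep(1, H), beta = numeric(H),
              b_out = numeric(K))
    if (M >= 1) {
      p$A <- array(stats::rnorm(H * K * M, 0, 0.3), dim = c(H, K, M))
      p$S <- array(2, dim = c(H, K, M))
      p$T <- array(stats::runif(H * K * M, 0, 2), dim = c(H, K, M))
    } else {
      p$W2 <- matrix(abs(stats::rnorm(H * K, 0, 1 / sqrt(H))), H, K)
    }
    structure(list(spec = spec, params = p,
                   run_mean = numeric(H), run_var = rep(1, H),
                   trained = FALSE),
              class = "parallel_net")
  })
}

# Forward pass. training = TRUE uses batch statistics for the normalization
# (and returns the intermediates needed for backpropagation); otherwise the
# stored running statistics are used.
network_forward <- function(net, X, training = FALSE) {
  p <- net$params; spec <- net$spec
  X <- as.matrix(X)
  if (ncol(X) != spec$d_in) stop("input dimension mismatch", call. = FALSE)
  U <- sweep(X %*% p$W1, 2, p$b1, "+")
  eps <- 1e-5
  if (training) {
    mu <- colMeans(U)
    va <- colMeans(sweep(U, 2, mu)^2)
  } else {
    mu <- net$run_mean; va <- net$run_var
  }
  Uhat <- sweep(sweep(U, 2, mu), 2, sqrt(va + eps), "/")
  Un <- sweep(sweep(Uhat, 2, p$gamma, "*"), 2, p$beta, "+")
  Hact <- softplus(Un)
  Z <- matrix(rep(p$b_out, each = nrow(X)), nrow(X), spec$d_out)
  if (spec$M >= 1) {
    for (h in seq_len(spec$d_hidden))
      for (k in seq_len(spec$d_out))
        for (j in seq_len(spec$M))
          Z[, k] <- Z[, k] + p$A[h, k, j]^2 *
            stats::plogis(p$S[h, k, j] * (Hact[, h] - p$T[h, k, j]))
  } else {
    Z <- Z + Hact %*% p$W2
  }
  list(Z = Z, Hact = Hact, Un = Un, Uhat = Uhat, mu = mu, va = va, U = U)
}

#' Train a parallel-synapse network
#'
#' Minibatch training of all parameters under softmax cross-entropy, with the
#' monotonicity constraints projected after every step: sigmoid slopes
#' `s >= 0` (parallel synapses) or nonnegative hidden-to-output weights
#' (linear network). Optimisation uses adaptive-moment gradient descent.
#'
#' @param spec a [network_spec()].
#' @param x training inputs (`n x d_in` matrix).
#' @param y integer class labels in `1..d_out` (or a factor).
#' @param x_test,y_test held-out data for the per-epoch accuracy trace;
#'   defaults to the training data.
#' @param epochs,batch_size,lr training hyperparameters.
#' @param seed integer seed (initialisation and batch shuffling).
#' @return A trained `parallel_net` with an `accuracy` trace (one value per
#'   epoch, on the held-out data).
#' @export
train_network <- function(spec, x, y, x_test = NULL, y_test = NULL,
                          epochs = 50, batch_size = 128, lr = 1e-3,
                          seed = 1L) {
  x <- as.matrix(x)
  y <- as.integer(as.factor(y))
  stopifnot(max(y) <= spec$d_out)
  if (is.null(x_test)) { x_test <- x; y_test <- y }
  else y_test <- as.integer(as.factor(y_test))
  net <- init_network(spec, seed = seed)
  adam <- list(m = list(), v = list(), t = 0)
  acc <- numeric(epochs)
  local_rng(derive_seed(seed, 3L), {
    for (ep in seq_len(epochs)) {
      ord <- sample.int(nrow(x))
      for (start in seq(1, nrow(x), by = batch_size)) {
        idx <- ord[start:min(start + batch_size - 1, nrow(x))]
        if (length(idx) < 2) next  # batch statistics need >= 2 rows
        upd <- network_gradients(net, x[idx, , drop = FALSE], y[idx])
        adam$t <- adam$t + 1
        for (nm in names(upd$grads)) {
          g <- upd$grads[[nm]]
          if (is.null(adam$m[[nm]])) { adam$m[[nm]] <- g * 0; adam$v[[nm]] <- g * 0 }
          adam$m[[nm]] <- 0.9 * adam$m[[nm]] + 0.1 * g
          adam$v[[nm]] <- 0.999 * adam$v[[nm]] + 0.001 * g^2
          mhat <- adam$m[[nm]] / (1 - 0.9^adam$t)
          vhat <- adam$v[[nm]] / (1 - 0.999^adam$t)
          net$params[[nm]] <- net$params[[nm]] - lr * mhat / (sqrt(vhat) + 1e-8)
        }
        # monotonicity projections
        if (spec$M >= 1) net$params$S[] <- pmax(net$params$S, 0)
        else net$params$W2[] <- pmax(net$params$W2, 0)
        # running statistics for evaluation-time normalization
        net$run_mean <- 0.9 * net$run_mean + 0.1 * upd$mu
        net$run_var <- 0.9 * net$run_var + 0.1 * upd$va
      }
      acc[ep] <- mean(predict(net, x_test) == y_test)
    }
  })
  net$trained <- TRUE
  net$accuracy <- acc
  net
}

# Softmax cross-entropy gradients for one minibatch (mean loss).
network_gradients <- function(net, X, y) {
  p <- net$params; spec <- net$spec
  fw <- network_forward(net, X, training = TRUE)
  B <- nrow(X)
  expZ <- exp(fw$Z - apply(fw$Z, 1, max))
  prob <- expZ / rowSums(expZ)
  dZ <- prob
  dZ[cbind(seq_len(B), y)] <- dZ[cbind(seq_len(B), y)] - 1
  dZ <- dZ / B
  g <- list(b_out = colSums(dZ))
  dH <- matrix(0, B, spec$d_hidden)
  if (spec$M >= 1) {
    gA <- array(0, dim(p$A)); gS <- array(0, dim(p$A)); gT <- array(0, dim(p$A))
    for (h in seq_len(spec$d_hidden)) {
      hv <- fw$Hact[, h]
      for (k in seq_len(spec$d_out)) {
        dzk <- dZ[, k]
        for (j in seq_len(spec$M)) {
          a <- p$A[h, k, j]; s <- p$S[h, k, j]; tt <- p$T[h, k, j]
          sig <- stats::plogis(s * (hv - tt))
          sp <- sig * (1 - sig)
          gA[h, k, j] <- sum(dzk * 2 * a * sig)
          gS[h, k, j] <- sum(dzk * a^2 * sp * (hv - tt))
          gT[h, k, j] <- sum(dzk * (-a^2) * sp * s)
          dH[, h] <- dH[, h] + dzk * a^2 * sp * s
        }
      }
    }
    g$A <- gA; g$S <- gS; g$T <- gT
  } else {
    g$W2 <- crossprod(fw$Hact, dZ)
    dH <- dZ %*% t(p$W2)
  }
  dUn <- dH * stats::plogis(fw$Un)        # softplus derivative
  g$gamma <- colSums(dUn * fw$Uhat)
  g$beta <- colSums(dUn)
  dUhat <- sweep(dUn, 2, p$gamma, "*")
  inv_sd <- 1 / sqrt(fw$va + 1e-5)
  dU <- sweep(dUhat, 2, colMeans(dUhat)) -
        fw$Uhat * matrix(rep(colMeans(dUhat * fw$Uhat), each = B), B)
  dU <- sweep(dU, 2, inv_sd, "*")
  g$W1 <- crossprod(X, dU)
  g$b1 <- colSums(dU)
  list(grads = g, mu = fw$mu, va = fw$va)
}

#' @param newdata input matrix.
#' @param type `"class"` for label indices, `"prob"` for softmax
#'   probabilities, `"logit"` for output pre-activations.
#' @rdname train_network
#' @export
predict.parallel_net <- function(object, newdata,
                                 type = c("class", "prob", "logit"), ...) {
  type <- match.arg(type)
  Z <- network_forward(object, as.matrix(newdata), training = FALSE)$Z
  if (type == "logit") return(Z)
  expZ <- exp(Z - apply(Z, 1, max))
  prob <- expZ / rowSums(expZ)
  if (type == "prob") prob else max.col(prob, ties.method = "first")
}

#' @export
print.parallel_net <- function(x, ...) {
  print(x$spec)
  if (isTRUE(x$trained))
    cat(sprintf("  trained %d epochs; final held-out accuracy %.3f\n",
                length(x$accuracy), x$accuracy[length(x$accuracy)]))
  invisible(x)
}

#' Synthetic image fixture for network sanity checks
#'
#' Tiny two-class "images": class 1 lights up the top half of a
#' `d_side x d_side` grid, class 2 the left half, plus uniform pixel noise.
#' The classes are linearly separable in expectation, so any sensible network
#' should reach high held-out accuracy quickly; this is a plumbing fixture,
#' not a model of natural images.
#'
#' @param n number of images.
#' @param d_side image side length (input dimension is `d_side^2`).
#' @param seed integer seed.
#' @return A list with `x` (`n x d_side^2` matrix) and `y` (labels 1/2).
#' @export
synthetic_digits <- function(n, d_side = 4, seed = 1L) {
  local_rng(seed, {
    tpl <- matrix(0, 2, d_side^2)
    m1 <- matrix(0, d_side, d_side); m1[1:(d_side %/% 2), ] <- 1
    m2 <- matrix(0, d_side, d_side); m2[, 1:(d_side %/% 2)] <- 1
    tpl[1, ] <- as.vector(m1); tpl[2, ] <- as.vector(m2)
    y <- sample(1:2, n, replace = TRUE)
    x <- tpl[y, , drop = FALSE] * 0.7 +
      matrix(stats::runif(n * d_side^2, 0, 0.3), n)
    list(x = x, y = y)
  })
}
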