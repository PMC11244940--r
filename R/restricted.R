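#' Control parameters for restricted-neuron training
#'
#' @param margin hinge margin `epsilon`: a pattern contributes to the gradient
#'   unless it is correctly classified with `(z - theta) y >= margin`.
#'   Default 0.1.
#' @param optimizer `"adam"` (default) applies the full-batch hinge gradient
#'   with adaptive per-parameter moment scaling; `"gd"` applies the literal
#'   explicit update rules with fixed rates. Both use the same violation set,
#'   the same synchronous gradient and the same resurrection rule. Plain
#'   fixed-rate descent is faithful to the update equations but needs far
#'   longer training on all but small problems, because the slope and
#'   threshold gradients carry an `a^2` prefactor that keeps them in a
#'   quasi-linear regime; see the package vignette.
#' @param lr learning rate of the adaptive-moment optimizer.
#' @param adam_beta2 second-moment decay of the adaptive-moment optimizer.
#'   The default 0.99 adapts faster than the textbook 0.999, which helps on
#'   the rapidly churning hinge violation set.
#' @param lr_patience,lr_factor reduce-on-plateau schedule for `"adam"`:
#'   whenever the best training-error count has not improved for another
#'   `lr_patience` epochs, the rate is multiplied by `lr_factor`.
#'   `lr_patience = 0` disables the schedule.
#' @param eta_a,eta_s,eta_t,eta_theta learning rates of the amplitude-root,
#'   slope, threshold and somatic-threshold updates under `optimizer = "gd"`.
#'   The updates are summed (not averaged) over the violation set, so on
#'   large problems these should scale like `1/P` (or set `normalize`).
#' @param normalize under `"gd"`, divide the summed gradient by the size of
#'   the violation set (mean instead of sum).
#' @param max_epochs epoch budget for the full-batch loop.
#' @param resurrect_every period (in epochs) of the dead-synapse check;
#'   `0` disables resurrection.
#' @param resurrection_floor amplitude floor: any synapse with `a^2` below it
#'   is reset to `a^2 = resurrection_floor` with a freshly drawn threshold.
#' @param patience stop early when the best training-error count has not
#'   improved for this many epochs; `0` disables.
#' @param beta_edge,beta_mid shape parameters of the edge-weighted threshold
#'   distribution used at resurrection: an equal mixture of
#'   `Beta(beta_edge, beta_mid)` and `Beta(beta_mid, beta_edge)`, U-shaped on
#'   `[0, 1]`, mimicking the learned concentration of thresholds near the
#'   input-range edges.
#' @param init_a_sd,init_s initialisation: `a ~ Normal(0, init_a_sd)`,
#'   `s = init_s`, `t ~ Uniform(0, 1)`, `theta = 0`.
#' @param seed integer seed for initialisation and resurrection draws.
#' @return A list of class `restricted_control`.
#' @export
restricted_control <- function(margin = 0.1,
                               optimizer = c("adam", "gd"),
                               lr = 0.01, adam_beta2 = 0.99,
                               lr_patience = 0L, lr_factor = 0.5,
                               eta_a = 0.01, eta_s = 0.01,
                               eta_t = 0.01, eta_theta = 0.01,
                               max_epochs = 20000L,
                               resurrect_every = 100L,
                               resurrection_floor = 0.01,
                               patience = 0L,
                               normalize = FALSE,
                               beta_edge = 0.5, beta_mid = 3,
                               init_a_sd = 0.3, init_s = 5,
                               seed = 1L) {
  optimizer <- match.arg(optimizer)
  stopifnot(margin > 0, lr > 0, eta_a > 0, eta_s > 0, eta_t > 0,
            eta_theta > 0, max_epochs >= 1, resurrection_floor > 0)
  structure(as.list(environment()), class = "restricted_control")
}

#' Create an untrained restricted neuron
#'
#' Allocates the `N x M` grid of synapse parameters with the default random
#' initialisation, in the zero-centred tanh parameterization used for
#' training.
#'
#' @param N number of input axons.
#' @param M number of parallel synapses per axon.
#' @param control a [restricted_control()] (supplies initialisation values and
#'   the seed).
#' @param form `"tanh"` (training form) or `"sigmoid"`.
#' @return An object of class `restricted_neuron`.
#' @export
new_restricted_neuron <- function(N, M, control = restricted_control(),
                                  form = c("tanh", "sigmoid")) {
  N <- check_count(N, "N"); M <- check_count(M, "M")
  form <- match.arg(form)
  init <- local_rng(control$seed, list(
    a = matrix(stats::rnorm(N * M, 0, control$init_a_sd), N, M),
    t = matrix(stats::runif(N * M), N, M)))
  structure(list(N = N, M = M,
                 a = init$a,
                 s = matrix(control$init_s, N, M),
                 t = init$t,
                 theta = 0,
                 form = form),
            class = "restricted_neuron")
}

#' Fit a restricted parallel-synapse neuron
#'
#' Trains a single model neuron that receives each of `N` axonal inputs
#' through `M` independent sigmoidal synapses, whose currents add at the soma
#' without any dendritic nonlinearity:
#' \deqn{z = \sum_{i=1}^{N} \sum_{j=1}^{M} a_{ij}^2\,
#'       \sigma(s_{ij}(x_i - t_{ij})), \qquad \hat y = sign(z - \theta).}
#' Training minimises the margin hinge loss
#' `sum(pmax(0, margin - (z - theta) * y))` by synchronous full-batch gradient
#' descent on all `3 N M + 1` parameters, with slopes projected to `s >= 0`
#' after every step. Periodically, synapses whose amplitude has collapsed
#' below a floor (and whose gradients have therefore vanished) are
#' "resurrected": their amplitude is raised to the floor and their threshold
#' redrawn from an edge-weighted distribution on the input range.
#'
#' Internally the optimisation runs in an equivalent zero-centred tanh
#' parameterization, which makes the somatic threshold easier to learn; use
#' [as_sigmoid_form()] to map the result to the nonnegative reporting form
#' (predictions are identical in both forms).
#'
#' @param x a [pattern_set][random_patterns], or a `P x N` input matrix.
#' @param y labels over `-1/+1` (ignored when `x` is a pattern set).
#' @param M number of parallel synapses per axon.
#' @param control a [restricted_control()].
#' @return An object of class `restricted_neuron` with components `N`, `M`,
#'   `a`, `s`, `t` (each `N x M`), `theta`, `form`, and a `fit` list recording
#'   `converged` (all patterns correct), `epochs`, `loss`, `train_errors` and
#'   `n_resurrected`.
#' @examples
#' ps <- pattern_fixture("sep2")
#' fit <- restricted_neuron(ps, M = 1, control = restricted_control(max_epochs = 2000))
#' fit$fit$converged
#' predict(fit, ps$x)
#' @seealso [unrestricted_neuron()] for the unlimited-synapse model,
#'   [estimate_capacity()] for the capacity protocol.
#' @export
restricted_neuron <- function(x, y = NULL, M = 2,
                              control = restricted_control()) {
  d <- as_xy(x, y)
  nrn <- new_restricted_neuron(ncol(d$x), M, control)
  out <- local_rng(derive_seed(control$seed, 1L),
    cpp_train_restricted(d$x, d$y, nrn$a, nrn$s, nrn$t, nrn$theta,
                         form_code(nrn$form), control$margin,
                         control$eta_a, control$eta_s, control$eta_t,
                         control$eta_theta,
                         as.integer(control$max_epochs),
                         as.integer(control$resurrect_every),
                         control$resurrection_floor,
                         control$beta_edge, control$beta_mid,
                         as.integer(control$patience),
                         isTRUE(control$normalize),
                         if (identical(control$optimizer, "adam")) 1L else 0L,
                         control$lr, as.integer(control$lr_patience),
                         control$lr_factor, control$adam_beta2))
  nrn$a <- out$a; nrn$s <- out$s; nrn$t <- out$t; nrn$theta <- out$theta
  nrn$fit <- list(converged = out$success, epochs = out$epochs,
                  loss = out$loss, train_errors = out$errors,
                  n_resurrected = out$n_resurrected)
  nrn$control <- control
  nrn$call <- match.call()
  nrn
}

form_code <- function(form) if (identical(form, "tanh")) 1L else 0L

#' Total somatic current of a model neuron
#'
#' The summed current `z` arriving at the soma for one or more input patterns:
#' the double sum of all per-synapse transmissions for a restricted neuron, or
#' the sum of per-axon staircase values for an unrestricted neuron. There is
#' no interaction across axons before the somatic threshold.
#'
#' @param object a fitted or unfitted neuron.
#' @param x a length-`N` input vector or a `P x N` matrix.
#' @param ... unused.
#' @return Numeric vector of currents, one per pattern.
#' @export
total_current <- function(object, x, ...) UseMethod("total_current")

#' @export
total_current.restricted_neuron <- function(object, x, ...) {
  x <- as_input_matrix(x, object$N)
  as.numeric(cpp_total_current(x, object$a, object$s, object$t,
                               form_code(object$form)))
}

as_input_matrix <- function(x, N) {
  if (inherits(x, "pattern_set")) x <- x$x
  if (is.null(dim(x))) x <- matrix(x, nrow = 1)
  x <- as.matrix(x)
  if (ncol(x) != N)
    stop(sprintf("input has %d columns but the neuron has %d axons",
                 ncol(x), N), call. = FALSE)
  storage.mode(x) <- "double"
  x
}

#' @param newdata input vector, matrix or pattern set.
#' @param type `"class"` for `-1/+1` labels, `"current"` for the raw somatic
#'   current `z`, `"margin"` for `z - theta`.
#' @rdname restricted_neuron
#' @export
predict.restricted_neuron <- function(object, newdata,
                                      type = c("class", "current", "margin"),
                                      ...) {
  type <- match.arg(type)
  z <- total_current(object, newdata)
  switch(type,
         current = z,
         margin = z - object$theta,
         class = ifelse(z - object$theta > 0, 1, -1))
}

#' Hinge loss and margin-violation set
#'
#' `hinge_loss()` evaluates the training objective
#' `sum(pmax(0, margin - (z - theta) y))`; it is zero exactly when every
#' pattern is classified correctly with margin at least `margin`.
#' `margin_violations()` returns the indices of the patterns with a strictly
#' positive hinge term — misclassified, or correct by less than the margin —
#' which is the set the gradient update sums over.
#'
#' @param object a neuron.
#' @param patterns a `pattern_set` (or matrix with `y` supplied).
#' @param y labels when `patterns` is a matrix.
#' @param margin hinge margin, default 0.1.
#' @return A nonnegative scalar / an integer index vector.
#' @export
hinge_loss <- function(object, patterns, y = NULL, margin = 0.1) {
  d <- as_xy(patterns, y)
  m <- (total_current(object, d$x) - object$theta) * d$y
  sum(pmax(0, margin - m))
}

#' @rdname hinge_loss
#' @export
margin_violations <- function(object, patterns, y = NULL, margin = 0.1) {
  d <- as_xy(patterns, y)
  m <- (total_current(object, d$x) - object$theta) * d$y
  which(margin - m > 0)
}

#' One synchronous full-batch gradient update
#'
#' Applies a single hinge-loss gradient step to all synapse parameters and the
#' somatic threshold. All partial sums run over the margin-violation set and
#' are evaluated at the pre-update parameter values; the slope is projected to
#' `s >= 0` afterwards. No resurrection check is performed.
#'
#' @param object a `restricted_neuron`.
#' @param patterns,y the training patterns.
#' @param control a [restricted_control()] supplying the margin and rates.
#' @return The updated neuron, with attribute `"n_violations"`.
#' @export
gradient_step <- function(object, patterns, y = NULL,
                          control = restricted_control()) {
  d <- as_xy(patterns, y)
  out <- cpp_gradient_step(d$x, d$y, object$a, object$s, object$t,
                           object$theta, form_code(object$form),
                           control$margin, control$eta_a, control$eta_s,
                           control$eta_t, control$eta_theta)
  object$a <- out$a; object$s <- out$s; object$t <- out$t
  object$theta <- out$theta
  attr(object, "n_violations") <- out$n_violations
  object
}

#' Resurrect dead synapses
#'
#' Synapses whose amplitude `a^2` falls below `floor` receive vanishing
#' gradients for all of their parameters and stop learning. This reset raises
#' each such amplitude to exactly `floor` (with `a = +sqrt(floor)`; the sign
#' of `a` is unidentifiable in `a^2`) and redraws its threshold from the
#' edge-weighted mixture `0.5 Beta(beta_edge, beta_mid) +
#' 0.5 Beta(beta_mid, beta_edge)` on `[0, 1]`. Slopes and live synapses are
#' untouched.
#'
#' @param object a `restricted_neuron`.
#' @param floor amplitude floor, default 0.01.
#' @param seed integer seed for the threshold draws.
#' @param beta_edge,beta_mid mixture shape parameters.
#' @return A list with `neuron` (the updated neuron) and `n_resurrected`.
#' @export
resurrect_synapses <- function(object, floor = 0.01, seed = 1L,
                               beta_edge = 0.5, beta_mid = 3) {
  dead <- which(object$a^2 < floor)
  if (length(dead)) {
    object$a[dead] <- sqrt(floor)
    object$t[dead] <- local_rng(seed, {
      pick <- stats::runif(length(dead)) < 0.5
      ifelse(pick, stats::rbeta(length(dead), beta_edge, beta_mid),
                   stats::rbeta(length(dead), beta_mid, beta_edge))
    })
  }
  list(neuron = object, n_resurrected = length(dead))
}

#' Aggregate transmission function of one axon
#'
#' The effective axon-to-soma input/output curve: the sum of the axon's `M`
#' parallel transmission functions evaluated on a grid. Nondecreasing by
#' construction (`s >= 0`, amplitudes squared).
#'
#' @param object a `restricted_neuron`.
#' @param axon axon index in `1..N`.
#' @param grid input values, default 101 points on `[0, 1]`.
#' @return Numeric vector of aggregate currents on `grid`.
#' @export
aggregate_transmission <- function(object, axon, grid = seq(0, 1, length.out = 101)) {
  stopifnot(axon >= 1, axon <= object$N)
  f <- if (identical(object$form, "tanh")) tanh_transmission else sigmoid_transmission
  out <- numeric(length(grid))
  for (j in seq_len(object$M))
    out <- out + f(grid, object$a[axon, j], object$s[axon, j], object$t[axon, j])
  out
}

#' @export
print.restricted_neuron <- function(x, ...) {
  cat(sprintf("Restricted parallel-synapse neuron (%s form): N = %d axons, M = %d synapses/axon\n",
              x$form, x$N, x$M))
  if (!is.null(x$fit))
    cat(sprintf("  trained: %s after %d epochs (loss %.4g, %d training errors, %d resurrections)\n",
                if (x$fit$converged) "all patterns classified" else "not converged",
                x$fit$epochs, x$fit$loss, x$fit$train_errors, x$fit$n_resurrected))
  cat(sprintf("  somatic threshold theta = %.4g\n", x$theta))
  invisible(x)
}

#' @export
summary.restricted_neuron <- function(object, ...) {
  amp <- if (identical(object$form, "tanh")) 2 * object$a^2 else object$a^2
  structure(list(neuron = object,
                 amplitude_quartiles = stats::quantile(amp),
                 threshold_quartiles = stats::quantile(object$t),
                 slope_quartiles = stats::quantile(abs(object$s))),
            class = "summary.restricted_neuron")
}

#' @export
print.summary.restricted_neuron <- function(x, ...) {
  print(x$neuron)
  cat("  amplitudes a^2 (sigmoid form):\n")
  print(signif(x$amplitude_quartiles, 4))
  cat("  thresholds t:\n")
  print(signif(x$threshold_quartiles, 4))
  invisible(x)
}

#' @export
coef.restricted_neuron <- function(object, ...) {
  data.frame(axon = rep(seq_len(object$N), object$M),
             synapse = rep(seq_len(object$M), each = object$N),
             a = as.vector(object$a),
             amplitude = as.vector(object$a^2),
             slope = as.vector(object$s),
             threshold = as.vector(object$t))
}

#' @param axons which axons' aggregate transmission functions to draw.
#' @rdname restricted_neuron
#' @export
plot.restricted_neuron <- function(x, axons = seq_len(min(x$N, 8)), ...) {
  grid <- seq(0, 1, length.out = 201)
  curves <- sapply(axons, function(i) aggregate_transmission(x, i, grid))
  graphics::matplot(grid, curves, type = "l", lty = 1,
                    xlab = "presynaptic activity",
                    ylab = "aggregate synaptic current", ...)
  invisible(x)
}

#' @export
residuals.restricted_neuron <- function(object, patterns, y = NULL, ...) {
  d <- as_xy(patterns, y)
  d$y - predict(object, d$x)
}
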