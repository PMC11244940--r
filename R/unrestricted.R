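#' Exact solver for the per-axon monotone staircase objective
#'
#' For one axon, order the P data points by their input value (index
#' `alpha = 1..P`) and let `I[alpha]` be the aggregate transmission function
#' value at the alpha-th input. The unrestricted model fits, independently per
#' axon, the regularized linear objective
#' \deqn{\min_I \; -\sum_\alpha y_\alpha w_\alpha I_\alpha +
#'       \lambda \sum_\alpha I_\alpha^2}
#' subject to the staircase constraint `0 = I[1] <= I[2] <= ... <= I[P]`
#' (nonnegative step sizes `rho^2`, so the function is nondecreasing).
#'
#' The exact minimizer is read off a convex envelope of the cumulative
#' label-weight walk `c[k] = sum(y[1:k] * w[1:k])`: plot the points
#' `(k, c[k])`, take their greatest convex minorant, and set each `I[alpha]`
#' to the minorant's segment slope at `alpha`, divided by `2 lambda` and
#' clipped below at zero. Steps occur exactly where the minorant touches the
#' walk, and each touching segment's value is the mean of `y w` over the
#' segment divided by `2 lambda` — which is the stationarity condition of the
#' objective on active steps.
#'
#' @param labels length-P vector over `-1/+1`, in order of ascending input
#'   value on this axon.
#' @param weights length-P vector of positive importance weights, same order.
#' @param lambda positive regularization coefficient discouraging large
#'   somatic currents.
#' @param mult optional positive integer multiplicities for tied inputs that
#'   have been merged to one knot: entry k then carries the summed label
#'   weight of its tied points in `labels[k] * weights[k]` and counts `mult[k]`
#'   times in the regularizer. Default: all distinct (`mult = 1`).
#' @return Length-P (or length-K, with `mult`) nondecreasing nonnegative
#'   vector of staircase values with first element 0.
#' @examples
#' envelope_solve(c(-1, 1), c(1, 1), lambda = 0.5)        # (0, 1)
#' envelope_solve(c(1, -1, 1), c(1, 1, 1), lambda = 0.5)  # (0, 0, 1)
#' @export
envelope_solve <- function(labels, weights, lambda, mult = NULL) {
  P <- length(labels)
  if (P == 0) return(numeric(0))
  if (!is.numeric(lambda) || length(lambda) != 1 || lambda <= 0)
    stop("'lambda' must be a positive number", call. = FALSE)
  if (length(weights) != P)
    stop("'labels' and 'weights' lengths differ", call. = FALSE)
  if (any(weights < 0)) stop("weights must be nonnegative", call. = FALSE)
  if (is.null(mult)) mult <- rep.int(1, P)
  envelope_core(labels * weights, mult, lambda)
}

# Greatest convex minorant of the cumulative walk of signed knot masses `u`
# at cumulative positions given by multiplicities `m`; returns knot values.
envelope_core <- function(u, m, lambda) {
  K <- length(u)
  if (K == 0) return(numeric(0))
  px <- cumsum(as.numeric(m))   # cumulative data-point count
  py <- cumsum(as.numeric(u))   # cumulative label-weight walk
  # lower convex hull (monotone chain) over (px, py); knot 1 anchors the hull
  hull <- integer(K)
  hull[1] <- 1L
  nh <- 1L
  for (k in seq_len(K)[-1]) {
    while (nh >= 2) {
      i <- hull[nh - 1L]; j <- hull[nh]
      # pop j if it lies on or above segment (i -> k)
      if ((px[j] - px[i]) * (py[k] - py[i]) -
          (py[j] - py[i]) * (px[k] - px[i]) <= 0) nh <- nh - 1L else break
    }
    nh <- nh + 1L
    hull[nh] <- k
  }
  hull <- hull[seq_len(nh)]
  vals <- numeric(K)
  for (seg in seq_len(nh - 1L)) {
    lo <- hull[seg]; hi <- hull[seg + 1L]
    slope <- (py[hi] - py[lo]) / (px[hi] - px[lo])
    vals[(lo + 1L):hi] <- max(0, slope / (2 * lambda))
  }
  cummax(vals)  # guards against roundoff-level inversions only
}

#' Evaluate one staircase axon
#'
#' A trained axon is a right-continuous step function: at a knot it returns
#' that knot's staircase value, between knots the value of the nearest knot to
#' the left, below the first knot 0, and above the last knot the final value.
#'
#' @param axon a list with `knots` (ascending) and `values` (nondecreasing,
#'   first element 0), as stored in an [unrestricted_neuron()].
#' @param x input values.
#' @return Aggregate synaptic current at each `x`.
#' @export
evaluate_axon <- function(axon, x) {
  idx <- findInterval(x, axon$knots)
  ifelse(idx == 0, 0, axon$values[pmax(idx, 1L)])
}

#' Control parameters for the unrestricted neuron
#'
#' @param lambda regularization coefficient of the per-axon objective;
#'   `NULL` (default) uses `1 / (2 P)` so staircase values are order one.
#' @param max_iter maximum number of outer reweighting iterations.
#' @param seed integer seed (recorded; the solver itself is deterministic).
#' @return A list of class `unrestricted_control`.
#' @export
unrestricted_control <- function(lambda = NULL, max_iter = 1000L, seed = 1L) {
  if (!is.null(lambda) && lambda <= 0) stop("'lambda' must be positive", call. = FALSE)
  structure(list(lambda = lambda, max_iter = as.integer(max_iter),
                 seed = as.integer(seed)),
            class = "unrestricted_control")
}

#' Fit an unrestricted parallel-synapse neuron
#'
#' The limiting model in which each axon may form arbitrarily many parallel
#' synapses, so that its aggregate transmission function becomes an arbitrary
#' nondecreasing staircase with up to one step per data point. Each axon's
#' staircase is fitted exactly by [envelope_solve()]; the somatic prediction
#' is `sign(sum_i I_i(x_i) - theta)`.
#'
#' Training iterates: (1) re-solve every axon's staircase under the current
#' per-pattern importance weights, (2) set the somatic threshold `theta` to
#' the midpoint of the best single split of the total currents (minimum
#' training errors, ties resolved toward fewer false positives), (3) increment
#' the weight of every still-misclassified pattern by one. The loop stops at
#' zero errors or after `max_iter` iterations.
#'
#' @param x a [pattern_set][random_patterns] or `P x N` input matrix.
#' @param y labels over `-1/+1` (ignored when `x` is a pattern set).
#' @param control an [unrestricted_control()].
#' @return An object of class `unrestricted_neuron`: a list with `N`, `P`,
#'   `axons` (per axon: `knots`, `values`, `steps`), `theta`, `weights` (final
#'   importance weights), `lambda`, and a `fit` list (`converged`,
#'   `iterations`, `train_errors`).
#' @examples
#' ps <- pattern_fixture("xor4")
#' fit <- unrestricted_neuron(ps)
#' fit$fit$converged
#' predict(fit, ps$x)
#' @export
unrestricted_neuron <- function(x, y = NULL, control = unrestricted_control()) {
  d <- as_xy(x, y)
  P <- nrow(d$x); N <- ncol(d$x)
  stopifnot(P >= 1)
  lambda <- if (is.null(control$lambda)) 1 / (2 * P) else control$lambda

  # per-axon sorted unique knots and each pattern's knot index
  ax_info <- lapply(seq_len(N), function(i) {
    knots <- sort(unique(d$x[, i]))
    list(knots = knots,
         gid = match(d$x[, i], knots),
         mult = tabulate(match(d$x[, i], knots), nbins = length(knots)))
  })

  w <- rep.int(1, P)
  iters <- 0L; errors <- P; converged <- FALSE
  values <- vector("list", N)
  z <- numeric(P); theta <- 0

  for (it in seq_len(control$max_iter)) {
    iters <- it
    yw <- d$y * w
    z[] <- 0
    for (i in seq_len(N)) {
      info <- ax_info[[i]]
      u <- as.vector(rowsum(yw, info$gid, reorder = TRUE))
      v <- envelope_core(u, info$mult, lambda)
      values[[i]] <- v
      z <- z + v[info$gid]
    }
    theta <- best_split_threshold(z, d$y)
    pred <- ifelse(z - theta > 0, 1, -1)
    wrong <- which(pred != d$y)
    errors <- length(wrong)
    if (errors == 0) { converged <- TRUE; break }
    w[wrong] <- w[wrong] + 1
  }

  axons <- lapply(seq_len(N), function(i) {
    v <- values[[i]]
    list(knots = ax_info[[i]]$knots, values = v, steps = diff(v))
  })
  structure(list(N = N, P = P, axons = axons, theta = theta, weights = w,
                 lambda = lambda,
                 fit = list(converged = converged, iterations = iters,
                            train_errors = errors),
                 call = match.call()),
            class = "unrestricted_neuron")
}

# Exact 1-D split of the currents: theta minimizing training errors for the
# rule "+1 iff z > theta"; ties broken toward fewer false positives.
best_split_threshold <- function(z, y) {
  o <- order(z)
  zs <- z[o]; ys <- y[o]
  P <- length(z)
  pos_below <- cumsum(ys > 0)                  # predicted -1 but labelled +1
  neg_above <- sum(ys < 0) - cumsum(ys < 0)    # predicted +1 but labelled -1
  # cut after position k (k = 0..P); only cuts between distinct z are valid
  errs <- c(sum(ys < 0), pos_below + neg_above)
  fp <- c(sum(ys < 0), neg_above)
  valid <- c(TRUE, zs[-P] < zs[-1], TRUE)
  errs[!valid] <- NA
  best <- which(errs == min(errs, na.rm = TRUE))
  k <- best[which.min(fp[best])] - 1L
  if (k == 0) zs[1] - 1 else if (k == P) zs[P] + 1 else (zs[k] + zs[k + 1]) / 2
}

#' @export
total_current.unrestricted_neuron <- function(object, x, ...) {
  x <- as_input_matrix(x, object$N)
  z <- numeric(nrow(x))
  for (i in seq_len(object$N))
    z <- z + evaluate_axon(object$axons[[i]], x[, i])
  z
}

#' @param newdata input vector, matrix or pattern set.
#' @param type `"class"`, `"current"` or `"margin"`, as for restricted neurons.
#' @rdname unrestricted_neuron
#' @export
predict.unrestricted_neuron <- function(object, newdata,
                                        type = c("class", "current", "margin"),
                                        ...) {
  type <- match.arg(type)
  z <- total_current(object, newdata)
  switch(type,
         current = z,
         margin = z - object$theta,
         class = ifelse(z - object$theta > 0, 1, -1))
}

#' Count the effective synapses of an unrestricted neuron
#'
#' The staircase parameterization allows up to one synapse (step) per data
#' point and axon, but trained neurons use far fewer. A step counts as an
#' effective synapse when its size exceeds 1/1000 of the maximum step size,
#' where the maximum is taken neuron-wide across all axons and the comparison
#' is strict. An untrained (all-flat) neuron has zero effective synapses on
#' every axon.
#'
#' @param object an `unrestricted_neuron`.
#' @return Integer vector of per-axon counts.
#' @export
effective_synapses <- function(object) {
  mx <- max(0, unlist(lapply(object$axons, `[[`, "steps")))
  vapply(object$axons,
         function(a) sum(a$steps > mx / 1000),
         integer(1))
}

#' @export
print.unrestricted_neuron <- function(x, ...) {
  cat(sprintf("Unrestricted parallel-synapse neuron: N = %d axons, trained on P = %d patterns\n",
              x$N, x$P))
  cat(sprintf("  %s after %d reweighting iterations (%d training errors); lambda = %.4g\n",
              if (x$fit$converged) "all patterns classified" else "not converged",
              x$fit$iterations, x$fit$train_errors, x$lambda))
  cat(sprintf("  effective synapses per axon: median %.1f (max %d)\n",
              stats::median(effective_synapses(x)), max(effective_synapses(x))))
  invisible(x)
}

#' @export
summary.unrestricted_neuron <- function(object, ...) {
  eff <- effective_synapses(object)
  structure(list(neuron = object, effective = eff,
                 weight_table = table(object$weights)),
            class = "summary.unrestricted_neuron")
}

#' @export
print.summary.unrestricted_neuron <- function(x, ...) {
  print(x$neuron)
  cat("  effective synapse counts per axon:\n")
  print(summary(x$effective))
  cat("  importance-weight histogram:\n")
  print(x$weight_table)
  invisible(x)
}

#' @export
coef.unrestricted_neuron <- function(object, ...) {
  do.call(rbind, lapply(seq_len(object$N), function(i) {
    a <- object$axons[[i]]
    data.frame(axon = i, knot = a$knots, value = a$values,
               step = c(0, a$steps))
  }))
}

#' @param axons which axons' staircases to draw.
#' @rdname unrestricted_neuron
#' @export
plot.unrestricted_neuron <- function(x, axons = seq_len(min(x$N, 8)), ...) {
  grid <- seq(0, 1, length.out = 401)
  curves <- sapply(axons, function(i) evaluate_axon(x$axons[[i]], grid))
  graphics::matplot(grid, curves, type = "s", lty = 1,
                    xlab = "presynaptic activity",
                    ylab = "aggregate synaptic current", ...)
  invisible(x)
}

#' @export
residuals.unrestricted_neuron <- function(object, patterns, y = NULL, ...) {
  d <- as_xy(patterns, y)
  d$y - predict(object, d$x)
}
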