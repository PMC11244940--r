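#' Run repeated random-pattern classification trials
#'
#' The raw material of a capacity estimate: for each problem size `P`, draw
#' fresh random pattern sets and record whether the model classified every
#' pattern correctly at the end of training ("success"). Every trial derives
#' its own seed from `seed`, recorded in the output, so any single trial can
#' be replayed.
#'
#' @param model `"restricted"`, `"unrestricted"` or `"perceptron"`.
#' @param N number of input axons.
#' @param M synapses per axon (restricted model only).
#' @param P_grid vector of problem sizes (numbers of patterns).
#' @param trials_per_P trials at each `P` (the reference protocol uses at
#'   least 5).
#' @param seed base seed from which all trial seeds derive.
#' @param control a [restricted_control()] or [unrestricted_control()] for the
#'   corresponding model; `NULL` for defaults.
#' @return A data frame with one row per trial: `model`, `N`, `M`, `P`,
#'   `load` (`P/N`), `seed`, `success`, `iters`.
#' @export
capacity_trials <- function(model = c("restricted", "unrestricted", "perceptron"),
                            N, M = 2, P_grid, trials_per_P = 5, seed = 1L,
                            control = NULL) {
  model <- match.arg(model)
  N <- check_count(N, "N")
  if (trials_per_P < 1 || length(P_grid) == 0)
    return(empty_trials())
  grid <- expand.grid(P = as.integer(P_grid), rep = seq_len(trials_per_P))
  rows <- lapply(seq_len(nrow(grid)), function(k) {
    P <- grid$P[k]
    trial_seed <- derive_seed(seed, P * 1000L + grid$rep[k])
    run_one_trial(model, N, M, P, trial_seed, control)
  })
  do.call(rbind, rows)
}

empty_trials <- function() {
  data.frame(model = character(), N = integer(), M = integer(),
             P = integer(), load = numeric(), seed = integer(),
             success = logical(), iters = integer())
}

#' Training configuration used for restricted-neuron capacity trials
#'
#' Capacity measurement trains near and beyond the model's convergence
#' frontier, which needs different settings than interactive fits: a steep
#' initial slope (the converged solutions are near-staircase, and starting
#' steep removes a long sharpening phase), a slower resurrection cadence
#' that gives the adaptive optimizer time between threshold reshuffles, a
#' 60000-epoch budget, and an early stop after 15000 epochs without a new
#' best error count.
#'
#' @param seed integer seed.
#' @return A [restricted_control()].
#' @export
restricted_capacity_control <- function(seed = 1L) {
  restricted_control(init_s = 20, resurrect_every = 500L,
                     max_epochs = 60000L, patience = 15000L, seed = seed)
}

run_one_trial <- function(model, N, M, P, trial_seed, control) {
  ps <- random_patterns(P, N, seed = trial_seed)
  if (model == "restricted") {
    ctrl <- if (is.null(control)) restricted_capacity_control() else control
    ctrl$seed <- derive_seed(trial_seed, 7L)
    fit <- restricted_neuron(ps, M = M, control = ctrl)
    success <- fit$fit$converged; iters <- fit$fit$epochs
  } else if (model == "unrestricted") {
    ctrl <- if (is.null(control)) unrestricted_control() else control
    fit <- unrestricted_neuron(ps, control = ctrl)
    success <- fit$fit$converged; iters <- fit$fit$iterations
  } else {
    success <- linearly_separable(ps$x, ps$y, bias = TRUE)
    iters <- 0L
  }
  data.frame(model = model, N = N, M = if (model == "restricted") M else NA_integer_,
             P = P, load = P / N, seed = trial_seed,
             success = success, iters = as.integer(iters))
}

#' Interpolate the classification capacity from trial records
#'
#' Fits a two-parameter logistic model of success probability against the
#' load `P/N` by maximum likelihood on the per-trial Bernoulli outcomes, and
#' reads off the capacity `P*/N` as the load at which the fitted success
#' probability crosses 50%. A nonparametric bootstrap (resampling trials with
#' replacement within each `P` stratum, refitting, and taking the 2.5–97.5
#' percentile interval of the refitted crossings) provides the confidence
#' interval.
#'
#' @param records a trial data frame from [capacity_trials()].
#' @param n_bootstrap number of bootstrap resamples (0 skips the interval).
#' @param seed seed for the bootstrap resampling.
#' @return An object of class `capacity_fit`: `pstar_over_N`, `ci_low`,
#'   `ci_high`, `n_bootstrap`, `load_grid` and `success_rates` (observed
#'   per-load rates), `coefficients` of the logistic fit, and `records`.
#' @examples
#' tr <- capacity_trials("perceptron", N = 10, P_grid = c(10, 20, 30, 40),
#'                       trials_per_P = 10, seed = 1)
#' fit_capacity(tr, n_bootstrap = 20)
#' @export
fit_capacity <- function(records, n_bootstrap = 100, seed = 1L) {
  est <- logistic_crossing(records)
  ci <- c(NA_real_, NA_real_)
  if (n_bootstrap >= 1)
    ci <- bootstrap_capacity(records, n_bootstrap = n_bootstrap, seed = seed)
  agg <- stats::aggregate(success ~ load, data = records, FUN = mean)
  structure(list(pstar_over_N = est$pstar,
                 ci_low = ci[1], ci_high = ci[2], n_bootstrap = n_bootstrap,
                 load_grid = agg$load, success_rates = agg$success,
                 coefficients = est$coef, records = records),
            class = "capacity_fit")
}

# Maximum-likelihood logistic fit of success ~ load; returns the 50% crossing.
logistic_crossing <- function(records) {
  if (length(unique(records$P)) < 2)
    stop("need trials at >= 2 distinct P values to interpolate the capacity",
         call. = FALSE)
  if (all(records$success) || !any(records$success))
    stop(paste("all trials succeeded or all failed; widen the P grid so it",
               "brackets the 50% success transition"), call. = FALSE)
  fit <- suppressWarnings(
    stats::glm(success ~ load, family = stats::binomial(), data = records))
  b <- stats::coef(fit)
  if (!all(is.finite(b)) || b[2] >= 0)
    stop("logistic fit is not monotone decreasing in the load; widen the P grid",
         call. = FALSE)
  list(pstar = unname(-b[1] / b[2]), coef = b)
}

#' @rdname fit_capacity
#' @export
bootstrap_capacity <- function(records, n_bootstrap = 100, seed = 1L) {
  stopifnot(n_bootstrap >= 1)
  strata <- split(seq_len(nrow(records)), records$P)
  draws <- local_rng(seed, {
    vapply(seq_len(n_bootstrap), function(b) {
      idx <- unlist(lapply(strata, function(ix)
        ix[sample.int(length(ix), length(ix), replace = TRUE)]))
      tryCatch(logistic_crossing(records[idx, ])$pstar,
               error = function(e) NA_real_)
    }, numeric(1))
  })
  if (mean(is.na(draws)) > 0.5)
    stop("more than half of the bootstrap resamples gave a degenerate fit",
         call. = FALSE)
  stats::quantile(draws, c(0.025, 0.975), na.rm = TRUE, names = FALSE)
}

#' Estimate a model's classification capacity
#'
#' The full protocol: pick a grid of problem sizes that brackets the 50%
#' success transition, run `trials_per_P` independent trials at each size,
#' fit the logistic success curve and interpolate `P*/N`, with a bootstrap
#' confidence interval.
#'
#' When `P_grid` is `NULL` the transition is bracketed adaptively: a coarse
#' doubling scan of the load with a few probe trials per point finds an
#' interval whose left end still succeeds in at least half the probes and
#' whose right end does not, the interval is tightened by bisection, and a
#' 5-point grid spanning it is then run at full `trials_per_P`. Probe trials
#' are kept in the records (they anchor the tails of the logistic fit).
#'
#' @inheritParams capacity_trials
#' @param P_grid explicit problem sizes, or `NULL` for adaptive bracketing.
#' @param probe_trials trials per point during the adaptive scan.
#' @param n_bootstrap bootstrap resamples for the confidence interval.
#' @return A `capacity_fit` (see [fit_capacity()]).
#' @examples
#' cap <- estimate_capacity("perceptron", N = 20, trials_per_P = 10,
#'                          n_bootstrap = 20, seed = 1)
#' cap$pstar_over_N
#' @export
estimate_capacity <- function(model = c("restricted", "unrestricted", "perceptron"),
                              N, M = 2, P_grid = NULL, trials_per_P = 5,
                              probe_trials = 5, n_bootstrap = 100, seed = 1L,
                              control = NULL) {
  model <- match.arg(model)
  probes <- empty_trials()
  if (is.null(P_grid)) {
    br <- bracket_transition(model, N, M, probe_trials, seed, control)
    probes <- br$trials
    P_grid <- unique(pmax(N %/% 4, round(seq(br$lo, br$hi, length.out = 5))))
  }
  main <- capacity_trials(model, N, M, P_grid, trials_per_P,
                          seed = derive_seed(seed, 999L), control = control)
  records <- rbind(probes, main)
  fit_capacity(records, n_bootstrap = n_bootstrap,
               seed = derive_seed(seed, 1234L))
}

# Coarse doubling scan + bisection until the bracketing loads are within a
# factor of ~1.5; returns the bracket and all probe trials run along the way.
bracket_transition <- function(model, N, M, probe_trials, seed, control) {
  all_trials <- list()
  probe <- function(P) {
    tr <- capacity_trials(model, N, M, P_grid = P,
                          trials_per_P = probe_trials,
                          seed = derive_seed(seed, P), control = control)
    all_trials[[length(all_trials) + 1L]] <<- tr
    mean(tr$success)
  }
  lo <- N
  if (probe(lo) < 0.5) { # capacity below load 1: scan downward
    hi <- lo
    lo <- max(2L, N %/% 2L)
    while (probe(lo) < 0.5 && lo > 2L) { hi <- lo; lo <- max(2L, lo %/% 2L) }
  } else {
    hi <- 2L * N
    while (probe(hi) >= 0.5) { lo <- hi; hi <- 2L * hi }
  }
  while (hi > 1.5 * lo) {
    mid <- as.integer(round((lo + hi) / 2))
    if (mid %in% c(lo, hi)) break
    if (probe(mid) >= 0.5) lo <- mid else hi <- mid
  }
  list(lo = lo, hi = hi, trials = do.call(rbind, all_trials))
}

#' @export
print.capacity_fit <- function(x, ...) {
  m <- x$records$model[1]
  cat(sprintf("Classification capacity (%s model, N = %d%s)\n",
              m, x$records$N[1],
              if (m == "restricted") sprintf(", M = %d", x$records$M[1]) else ""))
  cat(sprintf("  P*/N = %.3f", x$pstar_over_N))
  if (!is.na(x$ci_low))
    cat(sprintf("  [%.3f, %.3f] (%d-resample bootstrap, 95%%)",
                x$ci_low, x$ci_high, x$n_bootstrap))
  cat("\n")
  cat(sprintf("  %d trials over %d problem sizes, loads %.2f-%.2f\n",
              nrow(x$records), length(unique(x$records$P)),
              min(x$load_grid), max(x$load_grid)))
  invisible(x)
}

#' @export
plot.capacity_fit <- function(x, ...) {
  plot(x$load_grid, x$success_rates, pch = 19, ylim = c(0, 1),
       xlab = "load P/N", ylab = "success rate", ...)
  b <- x$coefficients
  curve(stats::plogis(b[1] + b[2] * x), add = TRUE, col = 2)
  graphics::abline(h = 0.5, v = x$pstar_over_N, lty = 3)
  invisible(x)
}
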