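#' Cover's function-counting probability
#'
#' The exact probability that `P` random points in general position in `D`
#' dimensions, with random binary labels, are separable by a homogeneous
#' linear threshold unit:
#' \deqn{f(P, D) = 2^{1-P} \sum_{k=0}^{D-1} \binom{P-1}{k}.}
#' It equals 1 for `P <= D` and exactly 1/2 at `P = 2D` — the classical
#' "two patterns per dimension" perceptron capacity. With a bias term the
#' effective dimension is `D = N + 1`.
#'
#' For moderate sizes the binomial sum is computed in exact double-precision
#' integer arithmetic; beyond that it switches to a numerically stable
#' log-space evaluation.
#'
#' @param P number of patterns (positive integer, vectorized).
#' @param D effective dimension (positive integer).
#' @return Probability in `[0, 1]`.
#' @examples
#' cover_fraction(3, 2)      # 0.75
#' cover_fraction(20, 10)    # exactly 0.5
#' @export
cover_fraction <- function(P, D) {
  P <- as.numeric(P); D <- as.numeric(D)
  stopifnot(all(P >= 1), all(D >= 1))
  mapply(function(p, d) {
    if (p <= d) return(1)
    if (p == 2 * d) return(0.5)  # binomial half-sum symmetry, exact at any size
    k <- 0:(d - 1)
    if (p - 1 <= 1020) {
      co <- choose(p - 1, k)
      if (all(co < 2^53) && sum(co) < 2^53)
        return(min(1, sum(co) * 2^(1 - p)))
    }
    # log-space fallback for large P
    lg <- lchoose(p - 1, k) + (1 - p) * log(2)
    m <- max(lg)
    min(1, exp(m) * sum(exp(lg - m)))
  }, P, D)
}

#' Test linear separability of a labelled pattern set
#'
#' Decides whether a weight vector (and optional bias) strictly separates the
#' two classes, i.e. whether a perceptron can classify the set perfectly.
#' Strict separability is scale invariant, so it is equivalent to feasibility
#' of the margin-1 system `y_mu (w . x_mu + b) >= 1`; that feasibility is
#' decided exactly by the hard-margin quadratic program
#' `min ||(w, b)||^2` subject to those constraints, which has a solution if
#' and only if the set is separable.
#'
#' @param x a [pattern_set][random_patterns] or `P x N` input matrix.
#' @param y labels over `-1/+1` (ignored when `x` is a pattern set).
#' @param bias include a bias term (effective dimension `N + 1`), matching
#'   the somatic threshold of the neuron models. Default `TRUE`.
#' @return `TRUE` or `FALSE`.
#' @examples
#' linearly_separable(pattern_fixture("sep2"))   # TRUE
#' linearly_separable(pattern_fixture("xor4"))   # FALSE
#' @export
linearly_separable <- function(x, y = NULL, bias = TRUE) {
  d <- as_xy(x, y)
  Z <- d$x * d$y                       # row-scale inputs by labels
  if (bias) Z <- cbind(Z, d$y)
  n <- ncol(Z)
  sol <- tryCatch(
    quadprog::solve.QP(Dmat = diag(n), dvec = rep(0, n),
                       Amat = t(Z), bvec = rep(1, nrow(Z))),
    error = function(e) {
      if (grepl("constraints are inconsistent", conditionMessage(e)))
        return(NULL)
      stop("separability QP failed: ", conditionMessage(e), call. = FALSE)
    })
  !is.null(sol)
}
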