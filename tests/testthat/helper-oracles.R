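# Independent oracles used across the suite. These deliberately take routes
# different from the package implementation: brute-force enumeration, generic
# least-squares solvers, and finite differences.

# Brute-force solver for the per-axon staircase objective
#   min -sum(y w I) + lambda sum(I^2),  0 = I[1] <= I[2] <= ... <= I[P].
# The optimum is piecewise constant; enumerate every partition of positions
# 2..P into consecutive blocks, give each block its clipped unconstrained
# optimum, keep feasible candidates, return the cheapest. Exact for small P.
oracle_staircase <- function(y, w, lambda) {
  P <- length(y)
  g <- y * w / (2 * lambda)
  if (P == 1) return(0)
  cost <- function(I) sum(-y * w * I + lambda * I^2)
  idx <- 2:P
  best <- NULL; best_cost <- Inf
  n_cuts <- P - 2  # cut points between consecutive positions in 2..P
  for (mask in 0:(2^n_cuts - 1)) {
    cuts <- if (n_cuts > 0) which(bitwAnd(mask, 2^(0:(n_cuts - 1))) > 0) else integer(0)
    bounds <- c(0, cuts, P - 1)  # block boundaries in index space of 2..P
    I <- numeric(P)
    ok <- TRUE; prev <- 0
    for (b in seq_len(length(bounds) - 1)) {
      block <- idx[(bounds[b] + 1):bounds[b + 1]]
      v <- max(0, mean(g[block]))
      if (v < prev - 1e-12) { ok <- FALSE; break }
      I[block] <- v; prev <- v
    }
    if (ok) {
      cc <- cost(I)
      if (cc < best_cost) { best_cost <- cc; best <- I }
    }
  }
  best
}

# Independent monotone-regression route: least-squares isotonic fit of the
# targets y*w/(2*lambda) on positions 2..P via stats::isoreg, clipped at zero
# (the first value is pinned to 0 and its target drops out of the objective).
oracle_isotonic <- function(y, w, lambda) {
  P <- length(y)
  g <- y * w / (2 * lambda)
  if (P == 1) return(0)
  fit <- stats::isoreg(seq_len(P - 1), g[-1])
  c(0, pmax(0, fit$yf))
}

# Central finite differences of the hinge loss with respect to every
# parameter of a restricted neuron.
oracle_hinge_gradient <- function(neuron, ps, margin, h = 1e-6) {
  f <- function(nrn) hinge_loss(nrn, ps, margin = margin)
  g <- list(a = neuron$a * 0, s = neuron$s * 0, t = neuron$t * 0)
  for (fld in c("a", "s", "t")) {
    for (k in seq_along(neuron[[fld]])) {
      up <- neuron; up[[fld]][k] <- up[[fld]][k] + h
      dn <- neuron; dn[[fld]][k] <- dn[[fld]][k] - h
      g[[fld]][k] <- (f(up) - f(dn)) / (2 * h)
    }
  }
  up <- neuron; up$theta <- up$theta + h
  dn <- neuron; dn$theta <- dn$theta - h
  g$theta <- (f(up) - f(dn)) / (2 * h)
  g
}

# Random restricted neuron with parameters away from hinge kinks.
random_neuron <- function(N, M, form = "tanh", seed = 1) {
  set.seed(seed)
  structure(list(N = N, M = M,
                 a = matrix(stats::rnorm(N * M, 0, 0.5), N, M),
                 s = matrix(stats::runif(N * M, 0.5, 6), N, M),
                 t = matrix(stats::runif(N * M), N, M),
                 theta = stats::rnorm(1, 0, 0.3),
                 form = form),
            class = "restricted_neuron")
}

new_pattern_set_for_test <- function(x, y) parsyn:::new_pattern_set(x, y)

# Homogeneous linear separability (no bias) by margin-1 feasibility QP;
# used to enumerate Cover's counting fraction directly.
separable_homogeneous <- function(x, y) {
  Z <- x * y
  ok <- tryCatch({
    quadprog::solve.QP(diag(ncol(Z)), rep(0, ncol(Z)), t(Z), rep(1, nrow(Z)))
    TRUE
  }, error = function(e) FALSE)
  ok
}
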