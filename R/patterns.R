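#' Generate a random binary classification problem
#'
#' Draws `P` input patterns of `N` axonal activities, each entry i.i.d.
#' Uniform(0, 1), with labels drawn i.i.d. from \{-1, +1\} with equal
#' probability. This is the benchmark ensemble used throughout the package to
#' measure classification capacity: a model neuron "solves" a pattern set when
#' it classifies every pattern correctly.
#'
#' Randomness is confined to one explicit, seeded generator per call; the
#' caller's RNG state is left untouched, so capacity trials can be replayed
#' individually from their recorded seeds.
#'
#' @param P number of patterns (rows), a positive integer.
#' @param N number of input axons (columns), a positive integer.
#' @param seed integer seed; recorded in the returned object.
#' @return An object of class `pattern_set`: a list with components
#'   `x` (`P` x `N` matrix, entries in `[0, 1]`, columns named `x1..xN`),
#'   `y` (length-`P` vector over `-1/+1`) and `seed`.
#' @examples
#' ps <- random_patterns(20, 5, seed = 1)
#' range(ps$x)
#' table(ps$y)
#' @export
random_patterns <- function(P, N, seed = 1L) {
  P <- check_count(P, "P")
  N <- check_count(N, "N")
  x <- local_rng(seed, {
    m <- matrix(stats::runif(P * N), nrow = P, ncol = N)
    y <- sample(c(-1, 1), P, replace = TRUE)
    list(m = m, y = y)
  })
  new_pattern_set(x$m, x$y, seed = seed)
}

new_pattern_set <- function(x, y, seed = NA_integer_) {
  x <- as.matrix(x)
  storage.mode(x) <- "double"
  y <- as.numeric(y)
  if (nrow(x) != length(y))
    stop("number of patterns and labels differ", call. = FALSE)
  if (length(y) && !all(y %in% c(-1, 1)))
    stop("labels must be -1 or +1", call. = FALSE)
  if (length(x) && (any(x < 0) || any(x > 1)))
    stop("inputs must lie in [0, 1]", call. = FALSE)
  colnames(x) <- paste0("x", seq_len(ncol(x)))
  structure(list(x = x, y = y, seed = seed), class = "pattern_set")
}

#' @export
print.pattern_set <- function(x, ...) {
  cat(sprintf("Pattern set: %d patterns x %d axons (%d labelled +1, %d labelled -1)\n",
              nrow(x$x), ncol(x$x), sum(x$y > 0), sum(x$y < 0)))
  invisible(x)
}

#' Small fixed pattern sets for examples and tests
#'
#' Hand-written datasets that are stable across releases:
#' \describe{
#'   \item{`"xor4"`}{an XOR-like configuration of four generic-position points
#'     in `[0,1]^2`, labels `(+1, -1, -1, +1)`; not linearly separable, so a
#'     perceptron must fail on it while two sigmoidal synapses per axon
#'     suffice. The coordinates are generic (no shared values, and neither +1
#'     point is coordinate-wise dominated by a -1 point) so the task is also
#'     solvable by additive monotone per-axon functions; on the exact 2 x 2
#'     grid version it provably would not be.}
#'   \item{`"sep2"`}{two points on one axon with labels `(+1, -1)`; linearly
#'     separable, solvable by a single synapse.}
#'   \item{`"fig2_toy"`}{four generic-position points in the unit square with
#'     mixed labels, illustrative of a small random classification task.}
#' }
#'
#' @param name one of `"xor4"`, `"sep2"`, `"fig2_toy"`.
#' @return A `pattern_set`.
#' @examples
#' pattern_fixture("xor4")
#' @export
pattern_fixture <- function(name) {
  switch(match.arg(name, c("xor4", "sep2", "fig2_toy")),
    xor4 = new_pattern_set(
      rbind(c(0.30, 0.35), c(0.10, 0.90), c(0.90, 0.10), c(0.85, 0.80)),
      c(1, -1, -1, 1)),
    sep2 = new_pattern_set(rbind(0.8, 0.2), c(1, -1)),
    fig2_toy = new_pattern_set(
      rbind(c(0.25, 0.30), c(0.70, 0.85), c(0.40, 0.65), c(0.85, 0.20)),
      c(1, -1, 1, -1)))
}

#' Write / read a pattern set as a CSV pair
#'
#' The on-disk form is two plain CSV files: the inputs (`P` rows, columns
#' `x1..xN`) and the labels (one column `y` over `-1/+1`). Values are written
#' with 17 significant digits so the round trip is lossless for doubles.
#'
#' @param ps a `pattern_set`.
#' @param inputs_file,labels_file paths of the two CSV files.
#' @return `write_patterns` returns the paths invisibly; `read_patterns`
#'   returns a `pattern_set`.
#' @export
write_patterns <- function(ps, inputs_file, labels_file) {
  stopifnot(inherits(ps, "pattern_set"))
  xi <- format(ps$x, digits = 17, trim = TRUE, scientific = FALSE)
  utils::write.table(xi, inputs_file, sep = ",", row.names = FALSE,
                     col.names = colnames(ps$x), quote = FALSE)
  utils::write.table(data.frame(y = ps$y), labels_file, sep = ",",
                     row.names = FALSE, quote = FALSE)
  invisible(c(inputs_file, labels_file))
}

#' @rdname write_patterns
#' @export
read_patterns <- function(inputs_file, labels_file) {
  x <- as.matrix(utils::read.csv(inputs_file, colClasses = "numeric"))
  y <- utils::read.csv(labels_file)$y
  new_pattern_set(x, y)
}

# --- shared helpers ---------------------------------------------------------

check_count <- function(x, what) {
  if (length(x) != 1 || !is.finite(x) || x < 1 || x != floor(x))
    stop(sprintf("'%s' must be a positive integer", what), call. = FALSE)
  as.integer(x)
}

# Evaluate `expr` under a private RNG stream seeded with `seed`, restoring the
# caller's RNG state afterwards.
local_rng <- function(seed, expr) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(as.integer(seed))
  force(expr)
}

# Derive a child seed from a base seed and an index; keeps results < 2^31.
derive_seed <- function(base, index) {
  as.integer((as.double(base) * 48271 + as.double(index) * 16807) %% 2147483587) + 1L
}

# Interpret a (patterns, labels) pair: accepts a pattern_set or matrix + labels.
as_xy <- function(x, y = NULL) {
  if (inherits(x, "pattern_set")) return(list(x = x$x, y = x$y))
  if (is.null(y)) stop("labels 'y' are required when 'x' is a matrix", call. = FALSE)
  x <- as.matrix(x)
  if (is.null(colnames(x))) colnames(x) <- paste0("x", seq_len(ncol(x)))
  list(x = x, y = as.numeric(y))
}
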