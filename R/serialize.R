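#' Save and restore a fitted neuron as JSON
#'
#' Plain-text persistence for both neuron models. A restricted neuron stores
#' `N`, `M`, the parameterization tag, `theta` and the per-synapse
#' `(a, s, t)` grids; an unrestricted neuron stores each axon's knots, values
#' and steps plus `theta` (the axon permutations are implied by the knots).
#' Numbers are written with 17 significant digits, so the round trip is
#' lossless for doubles.
#'
#' @param object a `restricted_neuron` or `unrestricted_neuron`.
#' @param path file path.
#' @return `write_neuron` returns `path` invisibly; `read_neuron` returns the
#'   neuron.
#' @export
write_neuron <- function(object, path) {
  if (inherits(object, "restricted_neuron")) {
    payload <- list(kind = "restricted", N = object$N, M = object$M,
                    form = object$form, theta = object$theta,
                    a = object$a, s = object$s, t = object$t)
  } else if (inherits(object, "unrestricted_neuron")) {
    payload <- list(kind = "unrestricted", N = object$N, P = object$P,
                    theta = object$theta, lambda = object$lambda,
                    axons = lapply(object$axons, function(ax)
                      list(knots = ax$knots, values = ax$values)))
  } else stop("not a neuron object", call. = FALSE)
  jsonlite::write_json(payload, path, digits = I(17), auto_unbox = TRUE)
  invisible(path)
}

#' @rdname write_neuron
#' @export
read_neuron <- function(path) {
  p <- jsonlite::read_json(path, simplifyVector = TRUE)
  if (identical(p$kind, "restricted")) {
    structure(list(N = as.integer(p$N), M = as.integer(p$M),
                   a = matrix(p$a, p$N, p$M), s = matrix(p$s, p$N, p$M),
                   t = matrix(p$t, p$N, p$M), theta = p$theta,
                   form = p$form),
              class = "restricted_neuron")
  } else if (identical(p$kind, "unrestricted")) {
    axons <- lapply(seq_len(nrow_or_len(p$axons)), function(i) {
      ax <- if (is.data.frame(p$axons)) list(knots = p$axons$knots[[i]],
                                             values = p$axons$values[[i]])
            else p$axons[[i]]
      list(knots = as.numeric(ax$knots), values = as.numeric(ax$values),
           steps = diff(as.numeric(ax$values)))
    })
    structure(list(N = as.integer(p$N), P = as.integer(p$P), axons = axons,
                   theta = p$theta, lambda = p$lambda,
                   fit = list(converged = NA, iterations = NA_integer_,
                              train_errors = NA_integer_)),
              class = "unrestricted_neuron")
  } else stop("unrecognised neuron file", call. = FALSE)
}

nrow_or_len <- function(x) if (is.data.frame(x)) nrow(x) else length(x)
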