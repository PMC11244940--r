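#' Synaptic transmission functions
#'
#' A single synapse converts presynaptic activity `x` into a somatic current
#' through a monotone sigmoidal transmission function with three learnable
#' parameters: an amplitude root `a` (the saturating current is `a^2`, squared
#' so it stays nonnegative during learning), a slope `s >= 0` and a threshold
#' `t` (the input at which the response rises fastest).
#'
#' `sigmoid_transmission()` is the reporting form
#' \deqn{h(x) = a^2 / (1 + e^{-s (x - t)}),}
#' bounded in `[0, a^2]` and equal to `a^2 / 2` at `x = t`.
#'
#' `tanh_transmission()` is the zero-centred form used internally during
#' training,
#' \deqn{h'(x) = 2 a'^2 / (1 + e^{-2 s' (x - t')}) - a'^2 = a'^2 \tanh(s'(x - t')),}
#' bounded in `[-a'^2, a'^2]` and antisymmetric about `x = t'`. The two forms
#' describe the same neuron up to a parameter map and a shift of the somatic
#' threshold; see [as_sigmoid_form()].
#'
#' All arguments recycle elementwise.
#'
#' @param x presynaptic activity (any real; the benchmark uses `[0, 1]`).
#' @param a,s,t amplitude root, slope (`>= 0`) and threshold.
#' @return Numeric vector of synaptic currents.
#' @examples
#' sigmoid_transmission(0.5, a = 1, s = 4, t = 0.5)  # a^2/2 = 0.5
#' tanh_transmission(0.5, a = 1, s = 1, t = 0.5)     # 0 at its threshold
#' @export
sigmoid_transmission <- function(x, a, s, t) {
  a^2 * stats::plogis(s * (x - t))
}

#' @rdname sigmoid_transmission
#' @export
tanh_transmission <- function(x, a, s, t) {
  a^2 * tanh(s * (x - t))
}

#' Convert a neuron from the tanh to the sigmoid parameterization
#'
#' Training runs in the zero-centred tanh form because a response centred on
#' zero makes the somatic threshold easier to learn; results are reported in
#' the nonnegative sigmoid form. Because `tanh(u) = 2 sigma(2u) - 1`, each
#' synapse maps as `a^2 = 2 a'^2`, `s = 2 s'`, `t = t'`, and the constant
#' offset `a'^2` absorbed per synapse shifts the somatic threshold to
#' `theta = theta' + sum(a'^2)`, which leaves the decision function
#' `z(x) - theta` unchanged for every input.
#'
#' @param object a [restricted_neuron] (or bare parameter list) in tanh form.
#' @return The same neuron in sigmoid form; predictions are identical.
#' @export
as_sigmoid_form <- function(object) {
  if (identical(object$form, "sigmoid")) return(object)
  if (!identical(object$form, "tanh"))
    stop("unknown parameterization tag: ", object$form, call. = FALSE)
  object$theta <- object$theta + sum(object$a^2)
  object$a <- sqrt(2) * object$a
  object$s <- 2 * object$s
  object$form <- "sigmoid"
  object
}
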