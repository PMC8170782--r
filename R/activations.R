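#' Exponential linear unit
#'
#' Elementwise `elu(x) = max(0, x) + min(0, exp(x) - 1)`: the identity for
#' non-negative inputs and a smooth saturation towards -1 for negative inputs.
#' Used throughout the prior-knowledge embedding.
#'
#' @param x A numeric vector, matrix or array; must be finite.
#' @return An object of the same shape as `x`.
#' @examples
#' elu(c(-1, 0, 2.5))
#' @export
elu <- function(x) {
  out <- x
  neg <- x < 0
  out[neg] <- exp(x[neg]) - 1
  out
}

# derivative of elu w.r.t. its (pre-activation) input
elu_grad <- function(x) {
  out <- array(1, dim = dim(x) %||% length(x))
  neg <- x < 0
  out[neg] <- exp(x[neg])
  if (is.null(dim(x))) out <- as.vector(out)
  out
}

#' Parametric rectified linear unit
#'
#' Elementwise `prelu(x) = max(0, x) + slope * min(0, x)`.  The default slope
#' of 0.25 is used in the predictor so the model can emit negative abundances,
#' as required for CLR-like (log-scale, centered) protein values.
#'
#' @param x A numeric vector, matrix or array.
#' @param slope Negative-branch slope (default 0.25).
#' @return An object of the same shape as `x`.
#' @examples
#' prelu(c(-4, 0, 3))   # -1, 0, 3
#' @export
prelu <- function(x, slope = 0.25) {
  out <- x
  neg <- x < 0
  out[neg] <- slope * x[neg]
  out
}

prelu_grad <- function(x, slope = 0.25) {
  out <- array(1, dim = dim(x) %||% length(x))
  out[x < 0] <- slope
  if (is.null(dim(x))) out <- as.vector(out)
  out
}

# elementwise logistic; large |x| saturates to 0/1 which is fine in doubles
sigmoid <- function(x) 1 / (1 + exp(-x))

# numerically stable softmax of a vector
softmax <- function(x) {
  e <- exp(x - max(x))
  e / sum(e)
}
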