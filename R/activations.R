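#' Rectified linear unit
#'
#' `f(x) = x` for `x >= 0`, `0` otherwise, applied elementwise. Dimensions of
#' array input are preserved.
#'
#' @param x numeric vector or array.
#' @return Object of the same shape as `x`.
#' @export
#' @examples
#' relu(c(-2, 0, 3))
relu <- function(x) {
  x * (x > 0)
}

#' SELU activation parameters
#'
#' The self-normalizing constants: `alpha ~= 1.6733`, `lambda ~= 1.0507`.
#' With these values the activation drives layer outputs toward zero mean and
#' unit variance for standard-normal inputs, which is what makes deep SELU
#' networks trainable without explicit normalization at every layer.
#'
#' @param alpha negative-branch scale.
#' @param lambda overall scale.
#' @return List with elements `alpha` and `lambda`.
#' @export
selu_params <- function(alpha = 1.6733, lambda = 1.0507) {
  stopifnot(is.numeric(alpha), is.numeric(lambda), alpha > 0, lambda > 0)
  list(alpha = alpha, lambda = lambda)
}

#' Scaled exponential linear unit
#'
#' `SELU(x) = lambda * x` for `x >= 0` and `lambda * (alpha * exp(x) - alpha)`
#' for `x < 0`, applied elementwise. Continuous at 0 and bounded below by
#' `-lambda * alpha`.
#'
#' @param x numeric vector or array.
#' @param params constants from [selu_params()].
#' @return Object of the same shape as `x`.
#' @export
#' @examples
#' selu(1)    # = lambda
#' selu(0)
#' selu(-20)  # ~ -lambda * alpha
selu <- function(x, params = selu_params()) {
  pos <- x >= 0
  params$lambda * (x * pos + (!pos) * (params$alpha * exp(pmin(x, 0)) - params$alpha))
}

# Derivative of SELU, elementwise (used by backprop).
selu_grad <- function(x, params = selu_params()) {
  pos <- x >= 0
  params$lambda * (pos + (!pos) * params$alpha * exp(pmin(x, 0)))
}
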