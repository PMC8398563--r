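#' Elementary activation functions
#'
#' The three activations used throughout the classifier benchmark:
#' `relu(z) = max(0, z)`, the logistic sigmoid `1 / (1 + exp(-z))`
#' (bounded in (0, 1)), and the softmax `exp(z_i) / sum_j exp(z_j)`
#' (computed with the max-subtraction trick for numerical stability).
#' All three are total functions applied elementwise; `softmax()` maps a
#' vector to a probability vector, or each row of a matrix when given one.
#'
#' @param z A numeric vector, matrix or array of finite values.
#' @return An object of the same shape as `z`. `softmax()` rows are
#'   positive and sum to one.
#' @examples
#' relu(c(-2, 0, 3))
#' sigmoid(0)
#' softmax(c(1, 1, 1))
#' @export
relu <- function(z) {
  z[z < 0] <- 0
  z
}

#' @rdname relu
#' @export
sigmoid <- function(z) {
  1 / (1 + exp(-z))
}

#' @rdname relu
#' @export
softmax <- function(z) {
  if (is.matrix(z)) {
    m <- apply(z, 1L, max)
    e <- exp(z - m)
    e / rowSums(e)
  } else {
    e <- exp(z - max(z))
    e / sum(e)
  }
}
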