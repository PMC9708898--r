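#' Numerically stable softmax
#'
#' @param a Numeric vector of logits, or a matrix whose columns are logit
#'   vectors.
#' @return Probabilities with the same shape as `a`; each (column) sums to 1.
#' @keywords internal
softmax <- function(a) {
  if (is.matrix(a)) {
    z <- exp(sweep(a, 2, apply(a, 2, max)))
    return(sweep(z, 2, colSums(z), "/"))
  }
  z <- exp(a - max(a))
  z / sum(z)
}

#' Logistic sigmoid and its derivative
#'
#' `sigmoid_prime(x)` is `sigmoid(x) * (1 - sigmoid(x))`, the surrogate for the
#' derivative of the spike threshold function.
#'
#' @param x Numeric.
#' @return Numeric of the same shape.
#' @export
sigmoid <- function(x) 1 / (1 + exp(-x))

#' @rdname sigmoid
#' @export
sigmoid_prime <- function(x) {
  s <- sigmoid(x)
  s * (1 - s)
}

# run expr under a temporary RNG seed without disturbing the caller's stream;
# seed = NULL leaves the RNG alone.
with_seed <- function(seed, expr) {
  if (is.null(seed)) return(expr)
  if (!exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    stats::runif(1)
  }
  old <- get(".Random.seed", envir = globalenv())
  on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  set.seed(seed)
  expr
}

`%||%` <- function(a, b) if (is.null(a)) b else a

stopifnot_scalar_number <- function(x, name) {
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x)) {
    stop(sprintf("`%s` must be a single finite number", name), call. = FALSE)
  }
}
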