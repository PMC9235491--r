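# Internal numerical and seeding helpers shared across modules.

`%||%` <- function(x, y) if (is.null(x)) y else x

#' Row-wise softmax with max subtraction
#'
#' Numerically stable softmax applied to each row of a matrix (or to a single
#' vector). Shift-invariant: adding a constant to a row leaves it unchanged.
#'
#' @param x numeric matrix (rows are logit vectors) or a single numeric vector.
#' @return matrix (or vector) of the same shape with non-negative rows summing
#'   to 1.
#' @export
softmax_rows <- function(x) {
  if (is.null(dim(x))) {
    z <- x - max(x)
    e <- exp(z)
    return(e / sum(e))
  }
  z <- x - apply(x, 1L, max)
  e <- exp(z)
  e / rowSums(e)
}

# log(sum(exp(x))) with the max subtracted; x a numeric vector.
logsumexp <- function(x) {
  m <- max(x)
  m + log(sum(exp(x - m)))
}

# Derive a reproducible 32-bit sub-seed from a master seed and a stream name,
# so parameter initialization, gene sampling and augmentation each consume an
# independent, named stream. Plain polynomial hash; stays below 2^31.
derive_seed <- function(seed, name) {
  h <- as.double(seed %% 2147483647L)
  for (cp in utf8ToInt(name)) h <- (h * 131 + cp) %% 2147483647
  as.integer(h)
}

stopf <- function(...) stop(sprintf(...), call. = FALSE)
warnf <- function(...) warning(sprintf(...), call. = FALSE)

# Check a numeric object is finite everywhere.
assert_finite <- function(x, what) {
  if (!all(is.finite(x))) stopf("non-finite values in %s", what)
  invisible(x)
}
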