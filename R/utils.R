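#' @importFrom methods new validObject is
#' @importFrom stats runif rnorm predict sd fft aggregate
#' @importFrom utils head read.csv write.csv
NULL

## Internal validation helpers. All user-facing errors funnel through these so
## messages carry the offending argument name.

.checkSignal <- function(x, min_len = 2L, arg = "x") {
  if (!is.numeric(x))
    stop(sprintf("'%s' must be a numeric vector", arg), call. = FALSE)
  if (length(x) < min_len)
    stop(sprintf("'%s' must have length >= %d", arg, min_len), call. = FALSE)
  if (!all(is.finite(x)))
    stop(sprintf("'%s' contains non-finite values", arg), call. = FALSE)
  invisible(as.numeric(x))
}

.checkCount <- function(n, min = 1L, arg = "n") {
  if (!is.numeric(n) || length(n) != 1L || !is.finite(n) || n != round(n) || n < min)
    stop(sprintf("'%s' must be a single integer >= %d", arg, min), call. = FALSE)
  as.integer(n)
}

#' Evaluate an expression under a temporary RNG seed
#'
#' All stochastic operations in the package route their randomness through this
#' helper so that a given (input, seed) pair is a pure function and the
#' caller's RNG stream is left untouched.
#'
#' @param seed single integer seed.
#' @param expr expression to evaluate.
#' @return the value of `expr`.
#' @keywords internal
.withSeed <- function(seed, expr) {
  seed <- .checkCount(seed, min = -.Machine$integer.max, arg = "seed")
  withr::with_seed(seed, expr, .rng_kind = "Mersenne-Twister",
                   .rng_normal_kind = "Inversion", .rng_sample_kind = "Rejection")
}

## Derive a stream of distinct 31-bit sub-seeds from one master seed.
.subSeeds <- function(seed, n) {
  .withSeed(seed, sample.int(.Machine$integer.max - 1L, n))
}
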