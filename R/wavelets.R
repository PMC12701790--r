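## Multilevel orthonormal discrete wavelet transform (periodic extension),
## written here because no installed R package provides wavelet transforms.
## The circular analysis/synthesis pair below is exactly orthonormal, so the
## inverse transform is the adjoint and reconstruction is exact to rounding.

.DWT_FILTERS <- list(
  haar = c(1, 1) / sqrt(2),
  d4 = c(1 + sqrt(3), 3 + sqrt(3), 3 - sqrt(3), 1 - sqrt(3)) / (4 * sqrt(2)),
  d6 = c(0.3326705529500825, 0.8068915093110924, 0.4598775021184914,
         -0.1350110200102546, -0.0854412738820267, 0.0352262918857095)
)

## Quadrature-mirror high-pass from the low-pass taps.
.qmf <- function(h) {
  L <- length(h)
  rev(h) * (-1)^(seq_len(L) - 1L)
}

.dwtStep <- function(x, h) {
  n <- length(x)
  g <- .qmf(h)
  half <- n %/% 2L
  lo <- numeric(half); hi <- numeric(half)
  base <- 2L * (seq_len(half) - 1L)
  for (k in seq_along(h)) {
    idx <- (base + k - 1L) %% n + 1L
    lo <- lo + h[k] * x[idx]
    hi <- hi + g[k] * x[idx]
  }
  list(lo = lo, hi = hi)
}

.idwtStep <- function(lo, hi, h) {
  n <- 2L * length(lo)
  g <- .qmf(h)
  x <- numeric(n)
  base <- 2L * (seq_along(lo) - 1L)
  for (k in seq_along(h)) {
    idx <- (base + k - 1L) %% n + 1L
    contrib <- h[k] * lo + g[k] * hi
    x[idx] <- x[idx] + contrib
  }
  x
}

#' Multilevel discrete wavelet decomposition
#'
#' Decomposes a vector to maximum depth with an orthonormal Daubechies filter
#' and periodic (circular) boundary handling. The input is zero-padded to the
#' next power of two; the original length is recorded so [idwtMultilevel()]
#' can undo the padding.
#'
#' @param x numeric vector (length >= 2).
#' @param family `"d4"` (default), `"haar"` or `"d6"`.
#' @return a list with `approx` (deepest approximation band), `detail` (list of
#'   detail bands, finest first), `family`, and `orig_length`.
#' @export
dwtMultilevel <- function(x, family = c("d4", "haar", "d6")) {
  family <- match.arg(family)
  x <- .checkSignal(x, min_len = 2L)
  h <- .DWT_FILTERS[[family]]
  n2 <- 2L^ceiling(log2(length(x)))
  xp <- c(x, numeric(n2 - length(x)))
  detail <- list()
  cur <- xp
  while (length(cur) >= 2L && length(cur) %% 2L == 0L) {
    st <- .dwtStep(cur, h)
    detail[[length(detail) + 1L]] <- st$hi
    cur <- st$lo
  }
  list(approx = cur, detail = detail, family = family, orig_length = length(x))
}

#' Inverse of [dwtMultilevel()]
#'
#' @param dec a decomposition as returned by [dwtMultilevel()].
#' @return the reconstructed vector, trimmed to the original length.
#' @export
idwtMultilevel <- function(dec) {
  h <- .DWT_FILTERS[[dec$family]]
  cur <- dec$approx
  for (d in rev(dec$detail)) cur <- .idwtStep(cur, d, h)
  cur[seq_len(dec$orig_length)]
}
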