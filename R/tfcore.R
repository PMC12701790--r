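## Discrete Wigner-Ville and smoothed pseudo Wigner-Ville distributions.
##
## Conventions (documented in the methods vignette):
##  * lag product A(n, m) = x(n + m) * x(n - m), integer lags m, indices outside
##    1..N contribute zero (feature vectors are not periodic);
##  * the lag axis is wrapped into an N-point DFT (negative lags stored at the
##    tail), so the output is N x N and frequency bin k corresponds to
##    normalized frequency k / (2N) cycles/sample -- the "doubled frequency"
##    convention: a sinusoid occupying DFT bin k0 of the signal localizes at
##    time-frequency bin 2 * k0;
##  * the lag product is symmetric in m, so the lag DFT is real up to rounding;
##    an imaginary residue above 1e-9 (relative) is a hard error.

.IMAG_TOL <- 1e-9

#' Instantaneous autocorrelation (lag-product) array
#'
#' Computes the symmetric instantaneous autocorrelation of a discrete signal,
#' `A[n, m] = x(n + m) * x(n - m)`, the quadratic kernel underlying the
#' Wigner-Ville distribution. Out-of-range indices contribute zero.
#'
#' @param x numeric vector, the discrete signal (length N >= 2, all finite).
#' @return an N x (2N-1) matrix; rows index time n = 1..N, columns index lag
#'   m = -(N-1)..(N-1) (column `N` is lag 0). Column names give the lag.
#' @examples
#' lagProductArray(c(0, 1, 0, 0))[2, ]  # impulse: only lag 0 at its own time
#' @export
lagProductArray <- function(x) {
  x <- .checkSignal(x)
  N <- length(x)
  lags <- -(N - 1L):(N - 1L)
  xp <- c(numeric(N - 1L), x, numeric(N - 1L))  # zero-padded, x[i] at xp[i + N - 1]
  A <- matrix(0, N, length(lags), dimnames = list(NULL, lags))
  n <- seq_len(N)
  for (j in seq_along(lags)) {
    m <- lags[j]
    A[, j] <- xp[n + m + N - 1L] * xp[n - m + N - 1L]
  }
  A
}

## Wrap the symmetric lag axis (columns -(N-1)..(N-1)) of a lag array into the
## N-point DFT layout: position 1 = lag 0, position m+1 = lag +m for
## m = 1..floor((N-1)/2), position N-m+1 = lag -m. Lags beyond +/-floor((N-1)/2)
## cannot be represented on an N-point grid without aliasing and are dropped;
## they are zero anyway whenever the effective lag support (boundary-limited or
## window-limited) fits, which holds for every interior evaluation.
.lagToDftLayout <- function(A) {
  N <- nrow(A)
  h <- (N - 1L) %/% 2L
  V <- matrix(0, N, N)
  zero <- N  # column of lag 0 in A
  V[, 1L] <- A[, zero]
  if (h >= 1L) {
    for (m in seq_len(h)) {
      V[, m + 1L] <- A[, zero + m]
      V[, N - m + 1L] <- A[, zero - m]
    }
  }
  V
}

## DFT over the lag axis (rows = time), with the imaginary-residue guard.
.lagDft <- function(V) {
  W <- t(stats::mvfft(t(V)))
  re <- Re(W); im <- Im(W)
  scale <- max(abs(re), 1)
  if (max(abs(im)) > .IMAG_TOL * scale)
    stop("lag DFT produced a non-negligible imaginary part; ",
         "the lag array is not symmetric", call. = FALSE)
  re
}

#' Plain discrete Wigner-Ville distribution
#'
#' DFT of the lag axis of [lagProductArray()]. Real-valued (the lag product is
#' even in the lag); can take negative values, as quadratic time-frequency
#' representations do. Serves as the degenerate, unsmoothed case of [swvd()].
#'
#' @inheritParams lagProductArray
#' @param analytic if `TRUE`, replace `x` by its discrete analytic signal
#'   (Hilbert transform) first. Default `FALSE`: feature vectors are fed as-is.
#' @return N x N real matrix; rows = time 1..N, columns = frequency bins
#'   0..N-1 in the doubled-frequency convention (see package vignette).
#' @export
wvdPlain <- function(x, analytic = FALSE) {
  x <- .checkSignal(x)
  if (analytic) x <- .analyticSignal(x)
  if (is.complex(x)) return(.wvdComplex(x))
  .lagDft(.lagToDftLayout(lagProductArray(x)))
}

## Complex-signal path (analytic preprocessing): A(n,m) = x(n+m) * Conj(x(n-m))
## is Hermitian in m, so the DFT is again real.
.wvdComplex <- function(x) {
  N <- length(x)
  h <- (N - 1L) %/% 2L
  xp <- c(complex(real = numeric(N - 1L)), x, complex(real = numeric(N - 1L)))
  n <- seq_len(N)
  V <- matrix(0 + 0i, N, N)
  V[, 1L] <- xp[n + N - 1L] * Conj(xp[n + N - 1L])
  for (m in seq_len(h)) {
    V[, m + 1L]     <- xp[n + m + N - 1L] * Conj(xp[n - m + N - 1L])
    V[, N - m + 1L] <- xp[n - m + N - 1L] * Conj(xp[n + m + N - 1L])
  }
  W <- t(stats::mvfft(t(V)))
  re <- Re(W); im <- Im(W)
  if (max(abs(im)) > 1e-7 * max(abs(re), 1))
    stop("analytic-signal WVD produced a non-negligible imaginary part", call. = FALSE)
  re
}

.analyticSignal <- function(x) {
  N <- length(x)
  X <- stats::fft(x)
  hmask <- numeric(N)
  if (N %% 2L == 0L) {
    hmask[1L] <- 1; hmask[N / 2L + 1L] <- 1
    hmask[2L:(N / 2L)] <- 2
  } else {
    hmask[1L] <- 1
    hmask[2L:((N + 1L) / 2L)] <- 2
  }
  stats::fft(X * hmask, inverse = TRUE) / N
}

#' Kaiser window
#'
#' Symmetric Kaiser taper of odd length with shape parameter `beta`;
#' `beta = 0` gives the rectangular window. Thin wrapper over
#' [signal::kaiser()] plus the validation this package's window specs require.
#'
#' @param M window size (positive integer; even sizes are bumped to the next
#'   odd integer so the window has a well-defined centre).
#' @param beta nonnegative shape parameter (main-lobe / side-lobe trade-off).
#' @return numeric vector of length `M` (after odd-bumping), symmetric, peak 1
#'   at the centre, all values in (0, 1].
#' @export
kaiserWindow <- function(M, beta = 0.5) {
  M <- .checkCount(M, min = 1L, arg = "M")
  if (!is.numeric(beta) || length(beta) != 1L || !is.finite(beta) || beta < 0)
    stop("'beta' must be a single nonnegative number", call. = FALSE)
  if (M %% 2L == 0L) M <- M + 1L
  if (M == 1L) return(1)
  as.numeric(signal::kaiser(M, beta))
}

#' Smoothed pseudo Wigner-Ville distribution
#'
#' The plain WVD smoothed by two independent windows: `g` is a centred,
#' unit-sum moving average over time applied to the lag-product array, and `H`
#' multiplies the lag axis (equivalently, convolves the frequency axis) before
#' the lag DFT. The point-wise absolute value is returned, so every entry is
#' nonnegative. With `g` of size 1 and an all-ones `H` spanning all lags the
#' result equals `abs(wvdPlain(x))`.
#'
#' @inheritParams wvdPlain
#' @param g time-smoothing window: either a numeric vector (odd length) or a
#'   single integer size, in which case a Kaiser window of that size is built.
#' @param H lag/frequency-smoothing window, same forms as `g`.
#' @param beta Kaiser shape parameter used when `g` / `H` are given as sizes.
#' @return N x N nonnegative matrix (same axes as [wvdPlain()]).
#' @examples
#' x <- sin(2 * pi * 5 * (0:31) / 32)
#' S <- swvd(x, g = 11, H = 15)
#' which.max(colSums(S)) - 1  # energy concentrates near doubled bin 10
#' @export
swvd <- function(x, g = 1L, H = NULL, beta = 0.5, analytic = FALSE) {
  x <- .checkSignal(x)
  N <- length(x)
  if (is.null(H)) H <- 2L * ((N - 1L) %/% 2L) + 1L  # full lag support
  g <- .asWindow(g, N, beta, "g")
  H <- .asWindow(H, N, beta, "H")
  if (analytic) x <- .analyticSignal(x)
  A <- if (is.complex(x)) .complexLagArray(x) else lagProductArray(x)
  A <- .smoothTime(A, g)
  A <- .applyLagWindow(A, H)
  V <- .lagToDftLayoutWide(A, N)
  if (is.complex(V)) {
    W <- t(stats::mvfft(t(V)))
    return(abs(Re(W)))
  }
  abs(.lagDft(V))
}

.asWindow <- function(w, N, beta, arg) {
  if (length(w) == 1L && is.numeric(w) && w == round(w)) {
    M <- .checkCount(w, min = 1L, arg = arg)
    if (M %% 2L == 0L) M <- M + 1L
    if (M > N) stop(sprintf("window '%s' (size %d) is longer than the signal (N = %d)",
                            arg, M, N), call. = FALSE)
    return(kaiserWindow(M, beta))
  }
  w <- .checkSignal(w, min_len = 1L, arg = arg)
  if (length(w) %% 2L != 1L)
    stop(sprintf("window '%s' must have odd length", arg), call. = FALSE)
  if (length(w) > N)
    stop(sprintf("window '%s' is longer than the signal (N = %d)", arg, N), call. = FALSE)
  w
}

.complexLagArray <- function(x) {
  N <- length(x)
  lags <- -(N - 1L):(N - 1L)
  xp <- c(complex(real = numeric(N - 1L)), x, complex(real = numeric(N - 1L)))
  A <- matrix(0 + 0i, N, length(lags), dimnames = list(NULL, lags))
  n <- seq_len(N)
  for (j in seq_along(lags)) {
    m <- lags[j]
    A[, j] <- xp[n + m + N - 1L] * Conj(xp[n - m + N - 1L])
  }
  A
}

## Centred weighted moving average over the time axis (rows), zero-padded ends,
## weights normalized to unit sum so smoothing preserves scale.
.smoothTime <- function(A, g) {
  if (length(g) == 1L) return(A)
  g <- g / sum(g)
  half <- (length(g) - 1L) %/% 2L
  N <- nrow(A)
  out <- A * 0
  for (j in seq_along(g)) {
    off <- j - half - 1L
    src <- seq_len(N) + off
    ok <- src >= 1L & src <= N
    out[ok, ] <- out[ok, ] + g[j] * A[src[ok], ]
  }
  out
}

## Multiply lag columns by the centred lag window; lags beyond its half-width
## are zeroed (that is what "pseudo" WVD means).
.applyLagWindow <- function(A, H) {
  lags <- as.integer(colnames(A))
  half <- (length(H) - 1L) %/% 2L
  w <- numeric(length(lags))
  inside <- abs(lags) <= half
  w[inside] <- H[lags[inside] + half + 1L]
  sweep(A, 2L, w, `*`)
}

## As .lagToDftLayout but tolerant of a window-truncated wide lag array.
.lagToDftLayoutWide <- function(A, N) {
  h <- (N - 1L) %/% 2L
  zero <- N
  cplx <- is.complex(A)
  V <- if (cplx) matrix(0 + 0i, N, N) else matrix(0, N, N)
  V[, 1L] <- A[, zero]
  if (h >= 1L) for (m in seq_len(h)) {
    V[, m + 1L] <- A[, zero + m]
    V[, N - m + 1L] <- A[, zero - m]
  }
  V
}

#' Per-time frequency localization of a time-frequency matrix
#'
#' Returns, for each time row, the frequency bin (0-based) with the largest
#' magnitude over the positive-frequency half excluding DC (bins 1..N/2-1).
#' Real signals produce a symmetric spectrum plus a known interference line at
#' DC between the positive- and negative-frequency components, so localization
#' is read off away from those bins.
#'
#' @param W an N x N time-frequency matrix ([wvdPlain()] or [swvd()] output).
#' @return integer vector of length N of 0-based bin indices.
#' @export
tfArgmaxBins <- function(W) {
  stopifnot(is.matrix(W), nrow(W) == ncol(W))
  N <- ncol(W)
  bins <- 2L:(N %/% 2L)  # columns for frequency bins 1 .. N/2 - 1
  apply(abs(W[, bins, drop = FALSE]), 1L, which.max)
}
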