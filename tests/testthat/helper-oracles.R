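# Independent oracles: brute-force / direct-sum implementations kept separate
# from the package's FFT and rank-based code paths.

# Lag-product array by explicit double loop.
lagArrayBrute <- function(x) {
  N <- length(x)
  A <- matrix(0, N, 2 * N - 1)
  for (n in seq_len(N)) for (j in seq_len(2 * N - 1)) {
    m <- j - N
    ip <- n + m; im <- n - m
    if (ip >= 1 && ip <= N && im >= 1 && im <= N) A[n, j] <- x[ip] * x[im]
  }
  A
}

# Direct-sum evaluation of the smoothed distribution: lag products, centred
# unit-sum time smoothing, multiplicative lag window, then an explicit DFT sum
# over lags m = -h..h (h = floor((N-1)/2)), absolute value. No FFT anywhere.
swvdDirect <- function(x, g, H) {
  N <- length(x)
  A <- lagArrayBrute(x)
  if (length(g) > 1L) {
    gn <- g / sum(g)
    hg <- (length(g) - 1L) %/% 2L
    As <- A * 0
    for (n in seq_len(N)) for (p in -hg:hg) {
      src <- n + p
      if (src >= 1 && src <= N) As[n, ] <- As[n, ] + gn[p + hg + 1L] * A[src, ]
    }
    A <- As
  }
  hh <- (length(H) - 1L) %/% 2L
  for (j in seq_len(2 * N - 1)) {
    m <- j - N
    A[, j] <- A[, j] * (if (abs(m) <= hh) H[m + hh + 1L] else 0)
  }
  abs(dftOverLags(A))
}

# Explicit DFT sum over lags m = -h..h (vectorized over m; no FFT).
dftOverLags <- function(A) {
  N <- nrow(A)
  h <- (N - 1L) %/% 2L
  W <- matrix(0, N, N)
  m <- seq_len(h)
  for (n in seq_len(N)) for (k in 0:(N - 1L)) {
    acc <- A[n, N] +
      sum(A[n, N + m] * exp(-2i * pi * k * m / N)) +
      sum(A[n, N - m] * exp(2i * pi * k * m / N))
    W[n, k + 1L] <- Re(acc)
  }
  W
}

# Plain WVD oracle: same direct DFT sum, no windows, signed output.
wvdDirect <- function(x) {
  dftOverLags(lagArrayBrute(x))
}

# Kaiser window by the zeroth-order modified Bessel series (base besselI).
kaiserDirect <- function(M, beta) {
  i <- 0:(M - 1)
  half <- (M - 1) / 2
  besselI(beta * sqrt(pmax(1 - ((i - half) / half)^2, 0)), 0) / besselI(beta, 0)
}

# AUC by brute-force positive-negative pair counting, ties half credit.
aucBrute <- function(scores, positive) {
  pos <- scores[positive]
  neg <- scores[!positive]
  tot <- 0
  for (p in pos) for (q in neg) tot <- tot + (p > q) + 0.5 * (p == q)
  tot / (length(pos) * length(neg))
}

makeTone <- function(N, k0, phase = 0) cos(2 * pi * k0 * (0:(N - 1)) / N + phase)
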