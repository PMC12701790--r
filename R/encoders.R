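## Vector-to-image encoders: the Wigner-Ville method (randomly sampled
## increasing Kaiser windows, one SWVD per channel), quadrant composition for
## long vectors, and the reshape / CWT / DWT baseline encoders. All encoders
## return an H x W x 3 array with attributes "encoder" and, for the Wigner
## method, "window_sizes".

#' Sample the three increasing Kaiser window sizes
#'
#' Draws the per-channel window sizes for the Wigner-Ville encoder:
#' `M1 ~ U(0.3N, 0.5N)`, `M2 ~ U(0.5N, 0.7N)`, `M3 ~ U(0.7N, 0.9N)`, each
#' rounded to the nearest odd integer (ties upward) so the smoothing windows
#' have a centre sample. The touching ranges give `M1 <= M2 <= M3`; the
#' increasing sizes break the symmetry between ensemble members that would
#' otherwise differ only by a swap of window sizes.
#'
#' @param N segment length the windows will smooth (N >= 10).
#' @param seed integer seed; the draw is a pure function of `(N, seed)`.
#' @return integer vector `c(M1, M2, M3)`, odd, nondecreasing.
#' @examples
#' sampleWindowSizes(100, seed = 1)
#' @export
sampleWindowSizes <- function(N, seed) {
  N <- .checkCount(N, min = 10L, arg = "N")
  u <- .withSeed(seed, stats::runif(3L, c(0.3, 0.5, 0.7) * N, c(0.5, 0.7, 0.9) * N))
  M <- .roundToOdd(u)
  M <- sort(M)  # rounding at a shared range endpoint cannot break the order, but be explicit
  pmax(M, 1L)
}

## Nearest odd integer, ties up: odd(x) = 2 * round((x - 1) / 2) + 1.
.roundToOdd <- function(x) {
  as.integer(2 * floor((x - 1) / 2 + 0.5) + 1)
}

#' Encode a feature vector as a Wigner-Ville image tensor
#'
#' Each channel `i` is the smoothed pseudo Wigner-Ville distribution of the
#' vector with a Kaiser window of size `Mi` used for both the time and the
#' frequency smoothing window. The three sizes are drawn by
#' [sampleWindowSizes()] unless supplied.
#'
#' @param x numeric feature vector (length N >= 10, finite).
#' @param seed integer seed for the window-size draw (ignored when
#'   `window_sizes` is given).
#' @param window_sizes optional integer triple `c(M1, M2, M3)` to reuse.
#' @param beta Kaiser shape parameter (default 0.5).
#' @return N x N x 3 nonnegative array, `attr(, "encoder") == "wigner"`,
#'   `attr(, "window_sizes")` the triple used.
#' @export
encodeWigner <- function(x, seed = 1L, window_sizes = NULL, beta = 0.5) {
  x <- .checkSignal(x, min_len = 10L)
  N <- length(x)
  if (is.null(window_sizes)) window_sizes <- sampleWindowSizes(N, seed)
  M <- vapply(window_sizes, .checkCount, integer(1), min = 1L, arg = "window_sizes")
  if (length(M) != 3L) stop("'window_sizes' must have length 3", call. = FALSE)
  out <- array(0, c(N, N, 3L))
  for (i in 1:3) out[, , i] <- swvd(x, g = M[i], H = M[i], beta = beta)
  structure(out, encoder = "wigner", window_sizes = as.integer(M))
}

#' Quadrant composition for long feature vectors
#'
#' Splits a long vector into four equal-length contiguous segments (zero-padded
#' at the end to a multiple of four), encodes each segment independently with
#' [encodeWigner()], and tiles the four N x N x 3 outputs as quadrants of one
#' (2N) x (2N) x 3 composite: segment 1 top-left, 2 top-right, 3 bottom-left,
#' 4 bottom-right.
#'
#' @param x numeric feature vector, length >= 40 (each segment needs >= 10).
#' @param seed integer seed; by default each segment draws its own window
#'   triple from a seed derived from it.
#' @param share_windows if `TRUE`, one window triple is drawn and reused by all
#'   four segments.
#' @param beta Kaiser shape parameter.
#' @return (2N) x (2N) x 3 array with attributes `encoder = "wigner_quadrant"`,
#'   `window_sizes` (a 4 x 3 matrix, one row per segment) and `segment_length`.
#' @export
quadrantCompose <- function(x, seed = 1L, share_windows = FALSE, beta = 0.5) {
  x <- .checkSignal(x, min_len = 40L)
  L <- length(x)
  Ns <- ceiling(L / 4)
  xp <- c(x, numeric(4L * Ns - L))
  segs <- split(xp, rep(1:4, each = Ns))
  seeds <- if (share_windows) rep(seed, 4L) else .subSeeds(seed, 4L)
  W <- if (share_windows) sampleWindowSizes(Ns, seed) else NULL
  enc <- lapply(1:4, function(i)
    encodeWigner(segs[[i]], seed = seeds[i], window_sizes = W, beta = beta))
  out <- array(0, c(2L * Ns, 2L * Ns, 3L))
  top <- seq_len(Ns); bot <- Ns + top
  out[top, top, ] <- enc[[1]]
  out[top, bot, ] <- enc[[2]]
  out[bot, top, ] <- enc[[3]]
  out[bot, bot, ] <- enc[[4]]
  structure(out, encoder = "wigner_quadrant",
            window_sizes = do.call(rbind, lapply(enc, attr, "window_sizes")),
            segment_length = Ns)
}

#' Reshape encoder
#'
#' Zero-pads the vector to the next perfect square s^2, fills an s x s grid
#' row-major, and replicates it to three identical channels.
#'
#' @param x numeric feature vector (length >= 4).
#' @return s x s x 3 array, `attr(, "encoder") == "reshape"`.
#' @export
encodeReshape <- function(x) {
  x <- .checkSignal(x, min_len = 4L)
  s <- ceiling(sqrt(length(x)))
  xp <- c(x, numeric(s * s - length(x)))
  M <- matrix(xp, s, s, byrow = TRUE)
  structure(array(rep(M, 3L), c(s, s, 3L)), encoder = "reshape")
}

#' Continuous-wavelet (Morlet scalogram) encoder
#'
#' Computes a magnitude scalogram of the vector with a Morlet wavelet over L
#' log-spaced scales (rows = scales, coarse to fine downward is reversed:
#' row 1 = smallest scale), giving an L x L matrix per channel. The three
#' channels use three Morlet centre-frequency parameters (5, 6, 8 rad/sample),
#' which trade time against frequency resolution.
#'
#' @param x numeric feature vector (length >= 10).
#' @param omega0 numeric length-3 vector of Morlet centre frequencies.
#' @return L x L x 3 nonnegative array, `attr(, "encoder") == "cwt"`.
#' @export
encodeCwt <- function(x, omega0 = c(5, 6, 8)) {
  x <- .checkSignal(x, min_len = 10L)
  stopifnot(length(omega0) == 3L)
  L <- length(x)
  scales <- exp(seq(log(1), log(L / 2), length.out = L))
  out <- array(0, c(L, L, 3L))
  for (i in 1:3) out[, , i] <- .morletScalogram(x, scales, omega0[i])
  structure(out, encoder = "cwt", scales = scales)
}

## |CWT| via FFT-based circular convolution with the (approximately analytic)
## Morlet wavelet, evaluated in the frequency domain: at scale s the wavelet's
## transfer function is exp(-(s*w - omega0)^2 / 2) on positive frequencies.
.morletScalogram <- function(x, scales, omega0) {
  L <- length(x)
  X <- stats::fft(x)
  w <- 2 * pi * (0:(L - 1)) / L
  w[w > pi] <- w[w > pi] - 2 * pi   # signed angular frequencies
  S <- matrix(0, length(scales), L)
  for (k in seq_along(scales)) {
    s <- scales[k]
    psi <- exp(-0.5 * (s * w - omega0)^2) * (w > 0) * sqrt(s)
    S[k, ] <- Mod(stats::fft(X * psi, inverse = TRUE) / L)
  }
  S
}

#' Discrete-wavelet (multilevel) encoder
#'
#' Runs a maximum-depth multilevel discrete wavelet decomposition of the
#' zero-padded vector and tiles the coefficients level-by-level (approximation
#' band first, then detail bands coarse to fine) row-major into a square grid,
#' zero-padding the remainder. The three channels use three orthogonal filter
#' families: Daubechies-4, Daubechies-2 (Haar) and Daubechies-6.
#'
#' @param x numeric feature vector (length >= 16).
#' @return s x s x 3 array, `attr(, "encoder") == "dwt"`.
#' @export
encodeDwt <- function(x) {
  x <- .checkSignal(x, min_len = 16L)
  fams <- list("d4", "haar", "d6")
  chans <- lapply(fams, function(f) {
    dec <- dwtMultilevel(x, family = f)
    unlist(c(list(dec$approx), rev(dec$detail)), use.names = FALSE)
  })
  len <- max(lengths(chans))
  s <- ceiling(sqrt(len))
  out <- array(0, c(s, s, 3L))
  for (i in 1:3) {
    v <- c(chans[[i]], numeric(s * s - length(chans[[i]])))
    out[, , i] <- matrix(v, s, s, byrow = TRUE)
  }
  structure(out, encoder = "dwt")
}

#' Train-anchored 0-255 feature normalization
#'
#' Per-feature affine map sending the training minimum to 0 and the training
#' maximum to 255, with parameters computed from the training rows only and
#' applied unchanged to any other partition. Values outside the training range
#' are extrapolated, not clipped. Constant features map to 0.
#'
#' @param train numeric matrix (samples x features), the training partition.
#' @param apply_to numeric matrix to transform (defaults to `train`).
#' @return matrix of the same shape as `apply_to`; the normalization
#'   parameters are attached as attributes `"shift"` and `"scale"`.
#' @export
normalize0255 <- function(train, apply_to = train) {
  .rangeNormalize(train, apply_to, hi = 255)
}

.rangeNormalize <- function(train, apply_to, hi) {
  stopifnot(is.matrix(train), is.matrix(apply_to),
            ncol(train) == ncol(apply_to), nrow(train) >= 1L)
  lo <- apply(train, 2L, min)
  rg <- apply(train, 2L, max) - lo
  scale <- ifelse(rg > 0, hi / rg, 0)  # constant features -> 0
  out <- sweep(sweep(apply_to, 2L, lo, `-`), 2L, scale, `*`)
  structure(out, shift = lo, scale = scale)
}

#' Draw and apply a feature permutation
#'
#' Draws one uniform random permutation of the feature columns and applies it
#' identically to every partition of the dataset, recording the permutation so
#' a run can be replayed.
#'
#' @param features numeric matrix (samples x features) or a list of such
#'   matrices sharing the same columns (e.g. `list(train = ..., test = ...)`).
#' @param seed integer seed.
#' @return the permuted matrix (or list), with attribute `"permutation"` (the
#'   column order applied; `features[, permutation]` reproduces the output).
#' @export
permuteFeatures <- function(features, seed) {
  one <- if (is.list(features)) features[[1L]] else features
  stopifnot(is.matrix(one))
  p <- .withSeed(seed, sample.int(ncol(one)))
  if (is.list(features)) {
    out <- lapply(features, function(m) {
      stopifnot(ncol(m) == length(p))
      m[, p, drop = FALSE]
    })
    return(structure(out, permutation = p))
  }
  structure(features[, p, drop = FALSE], permutation = p)
}

#' Bilinear resize of an image tensor
#'
#' Resizes each channel to `target_size` x `target_size` with bilinear
#' interpolation (edge-clamped sampling grid), for backbones with a fixed
#' input size. A no-op when the tensor is already at the target size.
#'
#' @param t H x W x 3 numeric array.
#' @param target_size integer >= 8.
#' @return target_size x target_size x 3 array (attributes preserved).
#' @export
resizeToBackbone <- function(t, target_size = 224L) {
  stopifnot(is.array(t), length(dim(t)) == 3L, dim(t)[3L] == 3L)
  target_size <- .checkCount(target_size, min = 8L, arg = "target_size")
  H <- dim(t)[1L]; W <- dim(t)[2L]
  if (H == target_size && W == target_size) return(t)
  out <- array(0, c(target_size, target_size, 3L))
  ri <- .bilinearIndex(H, target_size)
  ci <- .bilinearIndex(W, target_size)
  for (ch in 1:3) {
    M <- t[, , ch]
    out[, , ch] <- ri$w0 * (M[ri$i0, ci$i0] * ci$w0t + M[ri$i0, ci$i1] * ci$w1t) +
                   ri$w1 * (M[ri$i1, ci$i0] * ci$w0t + M[ri$i1, ci$i1] * ci$w1t)
  }
  attributes(out)[setdiff(names(attributes(t)), "dim")] <-
    attributes(t)[setdiff(names(attributes(t)), "dim")]
  out
}

## Align the centres of source and target pixel grids; returns neighbour
## indices and weights, with weight matrices pre-shaped for row (w0, w1 column
## vectors) and column (w0t, w1t row vectors) use.
.bilinearIndex <- function(n_src, n_dst) {
  pos <- (seq_len(n_dst) - 0.5) * n_src / n_dst + 0.5
  pos <- pmin(pmax(pos, 1), n_src)
  i0 <- pmin(floor(pos), n_src - 1L)
  if (n_src == 1L) i0 <- rep(1L, n_dst)
  frac <- pos - i0
  list(i0 = as.integer(i0), i1 = as.integer(pmin(i0 + 1L, n_src)),
       w0 = matrix(rep(1 - frac, n_dst), n_dst), w1 = matrix(rep(frac, n_dst), n_dst),
       w0t = matrix(rep(1 - frac, each = n_dst), n_dst),
       w1t = matrix(rep(frac, each = n_dst), n_dst))
}

#' Encode every row of a feature matrix
#'
#' Applies one encoder to each sample (row) of a feature matrix and stacks the
#' results into a 4D batch array. For the Wigner method one window triple is
#' drawn from `seed` and shared by all samples of the batch (the per-member
#' randomness of an ensemble lives in the member seed, not in the sample).
#'
#' @param features samples x features numeric matrix.
#' @param method one of `"wigner"`, `"reshape"`, `"cwt"`, `"dwt"`.
#' @param seed integer seed (wigner window draw).
#' @param quadrants use [quadrantCompose()] (wigner only; for long vectors).
#' @param target_size optional backbone input size; `NULL` keeps native size.
#' @param beta Kaiser shape parameter (wigner).
#' @return H x W x 3 x n_samples array; attribute `"encoder"` and, for wigner,
#'   `"window_sizes"`.
#' @export
encodeBatch <- function(features, method = c("wigner", "reshape", "cwt", "dwt"),
                        seed = 1L, quadrants = FALSE, target_size = NULL,
                        beta = 0.5) {
  method <- match.arg(method)
  stopifnot(is.matrix(features))
  n <- nrow(features)
  W <- NULL
  if (method == "wigner" && !quadrants)
    W <- sampleWindowSizes(ncol(features), seed)
  encodeOne <- function(x) {
    t <- switch(method,
      wigner = if (quadrants) quadrantCompose(x, seed = seed)
               else encodeWigner(x, window_sizes = W, beta = beta),
      reshape = encodeReshape(x),
      cwt = encodeCwt(x),
      dwt = encodeDwt(x))
    if (!is.null(target_size)) t <- resizeToBackbone(t, target_size)
    t
  }
  first <- encodeOne(features[1L, ])
  d <- dim(first)
  out <- array(0, c(d[1L], d[2L], 3L, n))
  out[, , , 1L] <- first
  if (n > 1L) for (i in 2:n) out[, , , i] <- encodeOne(features[i, ])
  structure(out, encoder = attr(first, "encoder"),
            window_sizes = attr(first, "window_sizes"))
}
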