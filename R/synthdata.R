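## Synthetic labeled feature-vector datasets with controllable class
## structure, so every pipeline stage is testable without external data.
## Two modes:
##   spectral   -- class c is a unit-amplitude sinusoid at frequency bin
##                 class_freqs[c] with uniform random phase plus Gaussian
##                 noise; classes differ in spectral content, so
##                 time-frequency encodings are discriminative by
##                 construction.
##   mean_shift -- standard Gaussian vectors; each class after the first
##                 adds `effect_size` on its own random 20% feature subset.

#' Generate a synthetic labeled dataset
#'
#' @param n_per_class samples per class.
#' @param len feature-vector length L (>= 16). The reference problems span
#'   roughly 64-3250 features.
#' @param mode `"spectral"` or `"mean_shift"`.
#' @param class_freqs integer frequency bins, one per class (spectral mode);
#'   must be distinct and < `len / 2`.
#' @param effect_size mean shift added for non-reference classes
#'   (mean_shift mode).
#' @param noise_sd Gaussian noise standard deviation.
#' @param seed integer seed; generation is a pure function of the settings.
#' @param train_frac fraction assigned to the training partition (stratified;
#'   default 0.5).
#' @return a `SummarizedExperiment` dataset (see [makeFeatureDataset()]) with
#'   the generator settings in `metadata()`.
#' @examples
#' se <- generateSynthData(20, 64, class_freqs = c(5, 12), noise_sd = 0.5, seed = 1)
#' table(sampleLabels(se), se$split)
#' @export
generateSynthData <- function(n_per_class = 200L, len = 64L,
                              mode = c("spectral", "mean_shift"),
                              class_freqs = c(5L, 12L), effect_size = 1,
                              noise_sd = 0.5, seed = 1L, train_frac = 0.5) {
  mode <- match.arg(mode)
  n_per_class <- .checkCount(n_per_class, min = 2L, arg = "n_per_class")
  len <- .checkCount(len, min = 16L, arg = "len")
  if (!is.numeric(noise_sd) || noise_sd < 0)
    stop("'noise_sd' must be >= 0", call. = FALSE)
  if (mode == "spectral") {
    class_freqs <- vapply(class_freqs, .checkCount, integer(1),
                          min = 1L, arg = "class_freqs")
    if (anyDuplicated(class_freqs) || any(class_freqs >= len / 2))
      stop("'class_freqs' must be distinct bins below len/2", call. = FALSE)
    K <- length(class_freqs)
  } else {
    K <- 2L
  }
  if (K < 2L) stop("need at least two classes", call. = FALSE)

  n <- n_per_class * K
  labels <- factor(rep(paste0("class", seq_len(K)), each = n_per_class))
  X <- .withSeed(seed, {
    M <- matrix(0, n, len)
    t_axis <- 0:(len - 1L)
    for (c in seq_len(K)) {
      rows <- (c - 1L) * n_per_class + seq_len(n_per_class)
      if (mode == "spectral") {
        phase <- stats::runif(n_per_class, 0, 2 * pi)
        base <- t(vapply(phase, function(p)
          sin(2 * pi * class_freqs[c] * t_axis / len + p), numeric(len)))
      } else {
        base <- matrix(0, n_per_class, len)
        if (c > 1L) {
          sub <- sample.int(len, max(1L, round(0.2 * len)))
          base[, sub] <- effect_size
        }
      }
      ## spectral: sinusoid + noise_sd-scaled noise; mean_shift: the unit
      ## Gaussian is the noise itself, shifted in mean for class > 1
      sdev <- if (mode == "spectral") noise_sd else 1
      M[rows, ] <- base + matrix(stats::rnorm(n_per_class * len, 0, sdev),
                                 n_per_class, len)
    }
    M
  })
  split <- rep("test", n)
  .withSeed(seed + 1L, {
    for (c in seq_len(K)) {
      rows <- which(labels == levels(labels)[c])
      tr <- sample(rows, round(train_frac * length(rows)))
      split[tr] <- "train"
    }
  })
  se <- makeFeatureDataset(X, labels, split)
  S4Vectors::metadata(se) <- list(mode = mode, n_per_class = n_per_class,
                                  len = len, class_freqs = if (mode == "spectral") class_freqs,
                                  effect_size = effect_size, noise_sd = noise_sd,
                                  seed = seed, train_frac = train_frac)
  se
}

#' Periodogram-peak oracle classifier
#'
#' Independent reference classifier for spectral-mode data: each sample is
#' assigned the class whose frequency bin carries the largest periodogram
#' magnitude. Quantifies the separability the generator guarantees.
#'
#' @param features samples x features matrix.
#' @param class_freqs the generator's class frequency bins.
#' @return factor of predicted class labels (`class1`, `class2`, ...).
#' @export
classifyByPeriodogram <- function(features, class_freqs) {
  stopifnot(is.matrix(features))
  P <- abs(stats::mvfft(t(features)))^2  # bins x samples
  pick <- apply(P[class_freqs + 1L, , drop = FALSE], 2L, which.max)
  factor(paste0("class", pick), levels = paste0("class", seq_along(class_freqs)))
}

#' Write small fixture tables
#'
#' Writes deterministic toy CSV tables (feature columns plus a `label`
#' column, optional `split` column) used by the unit tests and docs: a
#' spectral 2-class table (L = 64), a mean-shift table, and one long-vector
#' table (L = 256) exercising quadrant composition.
#'
#' @param dir output directory (created if missing).
#' @return invisibly, the paths written.
#' @export
fixtureTables <- function(dir = tempfile("wvdimage-fixtures-")) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  specs <- list(
    spectral_small = generateSynthData(10L, 64L, "spectral",
                                       class_freqs = c(5L, 12L),
                                       noise_sd = 0.5, seed = 101L),
    mean_shift_small = generateSynthData(10L, 32L, "mean_shift",
                                         effect_size = 1.5, seed = 102L),
    long_vector = generateSynthData(5L, 256L, "spectral",
                                    class_freqs = c(9L, 30L),
                                    noise_sd = 0.5, seed = 103L))
  paths <- vapply(names(specs), function(nm) {
    se <- specs[[nm]]
    df <- data.frame(featureMatrix(se), check.names = FALSE)
    df$label <- as.character(sampleLabels(se))
    df$split <- se$split
    p <- file.path(dir, paste0(nm, ".csv"))
    write.csv(df, p, row.names = FALSE)
    p
  }, character(1))
  invisible(paths)
}
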