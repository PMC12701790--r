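## Reading and writing the tool's interchange formats: CSV/TSV feature
## tables, sparse libsvm-style text, score CSVs, and PNG previews.

#' Read a labeled feature table
#'
#' Parses dense CSV/TSV (header row, a `label` column, optional `split`
#' column with `"train"`/`"test"`) or sparse libsvm-style text
#' (`label idx:value idx:value ...`, 1-based indices) into a dataset.
#' When the table carries no `split` column a stratified split is drawn.
#'
#' @param path file path.
#' @param format `"auto"` (by extension: `.tsv` tab, `.libsvm`/`.svm` sparse,
#'   else comma), `"csv"`, `"tsv"` or `"libsvm"`.
#' @param split_seed seed for the stratified split when none is stored.
#' @param train_frac training fraction for that split.
#' @return a `SummarizedExperiment` dataset.
#' @export
readFeatureTable <- function(path, format = c("auto", "csv", "tsv", "libsvm"),
                             split_seed = 1L, train_frac = 0.5) {
  format <- match.arg(format)
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  if (format == "auto") {
    ext <- tolower(tools::file_ext(path))
    format <- switch(ext, tsv = "tsv", libsvm = "libsvm", svm = "libsvm", "csv")
  }
  if (format == "libsvm") return(.readLibsvm(path, split_seed, train_frac))
  sep <- if (format == "tsv") "\t" else ","
  df <- read.csv(path, sep = sep, check.names = FALSE, stringsAsFactors = FALSE)
  if (!"label" %in% names(df))
    stop("feature table must contain a 'label' column", call. = FALSE)
  labels <- df$label
  split <- df$split
  feat <- df[setdiff(names(df), c("label", "split"))]
  bad <- which(!vapply(feat, is.numeric, logical(1)))
  if (length(bad))
    stop("non-numeric feature column(s): ",
         paste(names(feat)[bad], collapse = ", "), call. = FALSE)
  X <- as.matrix(feat)
  if (!all(is.finite(X))) {
    row <- which(!apply(is.finite(X), 1L, all))[1L]
    stop(sprintf("non-finite feature value at data line %d", row), call. = FALSE)
  }
  if (is.null(split))
    split <- .drawSplit(labels, split_seed, train_frac)
  makeFeatureDataset(X, labels, split)
}

.readLibsvm <- function(path, split_seed, train_frac) {
  lines <- readLines(path)
  lines <- lines[nzchar(trimws(lines))]
  if (!length(lines)) stop("empty libsvm file", call. = FALSE)
  parsed <- lapply(seq_along(lines), function(i) {
    tok <- strsplit(trimws(lines[i]), "[[:space:]]+")[[1L]]
    lab <- tok[1L]
    if (length(tok) == 1L) return(list(label = lab, idx = integer(), val = numeric()))
    kv <- strsplit(tok[-1L], ":", fixed = TRUE)
    if (any(lengths(kv) != 2L))
      stop(sprintf("malformed libsvm entry at line %d", i), call. = FALSE)
    idx <- suppressWarnings(as.integer(vapply(kv, `[`, "", 1L)))
    val <- suppressWarnings(as.numeric(vapply(kv, `[`, "", 2L)))
    if (anyNA(idx) || anyNA(val) || any(idx < 1L))
      stop(sprintf("malformed libsvm entry at line %d", i), call. = FALSE)
    list(label = lab, idx = idx, val = val)
  })
  p <- max(unlist(lapply(parsed, `[[`, "idx")), 0L)
  if (p == 0L) stop("libsvm file has no feature entries", call. = FALSE)
  X <- matrix(0, length(parsed), p,
              dimnames = list(NULL, paste0("f", seq_len(p))))
  for (i in seq_along(parsed))
    X[i, parsed[[i]]$idx] <- parsed[[i]]$val
  labels <- vapply(parsed, `[[`, "", "label")
  makeFeatureDataset(X, labels, .drawSplit(labels, split_seed, train_frac))
}

.drawSplit <- function(labels, seed, train_frac) {
  labels <- as.factor(labels)
  split <- rep("test", length(labels))
  .withSeed(seed, {
    for (lv in levels(labels)) {
      rows <- which(labels == lv)
      split[sample(rows, round(train_frac * length(rows)))] <- "train"
    }
  })
  split
}

#' Write / read a score matrix as CSV
#'
#' Scores round-trip losslessly (values serialized at full precision).
#'
#' @param scores samples x classes score matrix.
#' @param path file path.
#' @return `readScores()` returns the matrix; `writeScores()` the path,
#'   invisibly.
#' @export
writeScores <- function(scores, path) {
  stopifnot(is.matrix(scores))
  df <- as.data.frame(scores)
  if (is.null(colnames(scores)))
    names(df) <- paste0("class", seq_len(ncol(scores)))
  utils::write.table(df, path, sep = ",", row.names = FALSE, qmethod = "double")
  invisible(path)
}

#' @rdname writeScores
#' @export
readScores <- function(path) {
  df <- read.csv(path, check.names = FALSE)
  as.matrix(df)
}

#' Render a time-frequency matrix to PNG
#'
#' Debug view of a [swvd()] / [wvdPlain()] output (or one channel of an
#' encoder tensor): magnitudes are scaled to 0-255, written with time 1 at
#' the top row and frequency bin 0 at the left column. The orientation and
#' scaling are recorded in a JSON sidecar.
#'
#' @param W numeric matrix (rows = time, columns = frequency bins).
#' @param path output PNG path.
#' @return invisibly, the path.
#' @export
writeTfPng <- function(W, path) {
  if (!requireNamespace("png", quietly = TRUE))
    stop("the 'png' package is required for PNG export", call. = FALSE)
  stopifnot(is.matrix(W))
  A <- abs(W)
  rng <- range(A)
  img <- if (diff(rng) > 0) (A - rng[1L]) / diff(rng) else A * 0
  png::writePNG(img, path)
  jsonlite::write_json(
    list(rows = "time, index 1 at top", cols = "frequency bin, 0 at left",
         scale_min = rng[1L], scale_max = rng[2L]),
    paste0(path, ".json"), auto_unbox = TRUE, digits = NA)
  invisible(path)
}
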