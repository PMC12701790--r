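## Labeled feature tables travel as SummarizedExperiment objects:
## assay "features" is features x samples, colData carries `label` (factor)
## and `split` ("train" / "test"). These helpers hide the orientation.

#' Build a feature dataset
#'
#' Wraps a samples x features matrix, labels and a train/test assignment into
#' a `SummarizedExperiment` (assay `"features"`, features x samples).
#'
#' @param features samples x features numeric matrix.
#' @param labels vector coercible to factor, one per sample.
#' @param split character vector of `"train"` / `"test"`, one per sample.
#' @return a `SummarizedExperiment`.
#' @export
makeFeatureDataset <- function(features, labels, split) {
  stopifnot(is.matrix(features), nrow(features) == length(labels),
            length(split) == length(labels), all(split %in% c("train", "test")))
  if (!all(is.finite(features)))
    stop("'features' contains non-finite values", call. = FALSE)
  if (is.null(colnames(features)))
    colnames(features) <- paste0("f", seq_len(ncol(features)))
  if (is.null(rownames(features)))
    rownames(features) <- paste0("s", seq_len(nrow(features)))
  SummarizedExperiment::SummarizedExperiment(
    assays = list(features = t(features)),
    colData = S4Vectors::DataFrame(label = factor(labels), split = split))
}

#' @rdname makeFeatureDataset
#' @param se a dataset built by `makeFeatureDataset()`.
#' @param split_name `"train"`, `"test"` or `NULL` for all samples.
#' @return `featureMatrix()`: samples x features matrix; `sampleLabels()`:
#'   factor of labels (levels shared across partitions).
#' @export
featureMatrix <- function(se, split_name = NULL) {
  m <- t(SummarizedExperiment::assay(se, "features"))
  if (is.null(split_name)) return(m)
  m[se$split == split_name, , drop = FALSE]
}

#' @rdname makeFeatureDataset
#' @export
sampleLabels <- function(se, split_name = NULL) {
  l <- se$label
  if (is.null(split_name)) l else l[se$split == split_name]
}
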