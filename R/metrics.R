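## Evaluation metrics: AUC for 2-class problems, accuracy by argmax for
## multi-class, and the stratified k-fold protocol helper.

#' Area under the ROC curve
#'
#' Mann-Whitney formulation: the probability that a random positive outscores
#' a random negative, with ties counted half. Computed from the rank sum of
#' the positive scores.
#'
#' @param scores numeric vector of scores for the positive class.
#' @param positive logical vector (or 2-level factor whose second level is
#'   positive) aligned with `scores`.
#' @return AUC in \[0, 1\].
#' @examples
#' aucScore(c(0.9, 0.8, 0.3, 0.2), c(TRUE, TRUE, FALSE, FALSE))  # 1
#' @export
aucScore <- function(scores, positive) {
  if (is.factor(positive)) positive <- positive == levels(positive)[2L]
  positive <- as.logical(positive)
  stopifnot(length(scores) == length(positive), all(!is.na(positive)))
  np <- sum(positive); nn <- sum(!positive)
  if (np == 0L || nn == 0L)
    stop("AUC needs both classes present", call. = FALSE)
  r <- rank(scores)  # average ranks give ties half credit
  (sum(r[positive]) - np * (np + 1) / 2) / (np * nn)
}

#' Accuracy by argmax
#'
#' @param scores samples x classes score matrix; column order (or names) must
#'   match the label levels.
#' @param labels factor of true labels.
#' @return fraction of samples whose argmax column equals the true label.
#' @export
accuracyScore <- function(scores, labels) {
  labels <- as.factor(labels)
  stopifnot(nrow(scores) == length(labels))
  cols <- if (!is.null(colnames(scores))) match(levels(labels), colnames(scores))
          else seq_len(nlevels(labels))
  if (anyNA(cols)) stop("score columns do not cover all label levels", call. = FALSE)
  pred <- max.col(scores[, cols, drop = FALSE], ties.method = "first")
  mean(pred == as.integer(labels))
}

#' Evaluate a score matrix against labels
#'
#' Uses the protocol's performance indicator: AUC for 2-class problems (score
#' of the second factor level), accuracy by argmax otherwise.
#'
#' @inheritParams accuracyScore
#' @return named list with `metric` (`"auc"` or `"accuracy"`) and `value`.
#' @export
evaluateScores <- function(scores, labels) {
  labels <- as.factor(labels)
  if (nlevels(labels) == 2L) {
    col <- if (!is.null(colnames(scores))) match(levels(labels)[2L], colnames(scores)) else 2L
    list(metric = "auc", value = aucScore(scores[, col], labels))
  } else {
    list(metric = "accuracy", value = accuracyScore(scores, labels))
  }
}

#' Stratified k-fold assignment
#'
#' Assigns each sample to one of `k` folds, balancing class counts across
#' folds (each class is shuffled and dealt round-robin).
#'
#' @param labels factor of class labels.
#' @param k number of folds (default 10, the testing protocol's value).
#' @param seed integer seed.
#' @return integer vector of fold ids in `1..k`.
#' @export
stratifiedFolds <- function(labels, k = 10L, seed = 1L) {
  labels <- as.factor(labels)
  k <- .checkCount(k, min = 2L, arg = "k")
  fold <- integer(length(labels))
  .withSeed(seed, {
    for (lv in levels(labels)) {
      idx <- which(labels == lv)
      idx <- idx[sample.int(length(idx))]
      fold[idx] <- rep_len(seq_len(k), length(idx))
    }
  })
  fold
}
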