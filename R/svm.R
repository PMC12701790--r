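## The optimized SVM reference classifier: radial kernel, grid search over
## (cost, gamma) with stratified 5-fold cross-validation internal to the
## training partition, and [0,1] min-max normalization whose parameters come
## from the training rows only.

#' Default SVM hyperparameter grid
#'
#' Standard libsvm-style log2 grids: cost 2^(-5..15), gamma 2^(-15..3), step 2.
#'
#' @param cost,gamma numeric vectors of candidate values.
#' @return list with `cost` and `gamma`.
#' @export
svmGrid <- function(cost = 2^seq(-5, 15, by = 2), gamma = 2^seq(-15, 3, by = 2)) {
  stopifnot(length(cost) >= 1L, length(gamma) >= 1L, all(cost > 0), all(gamma > 0))
  list(cost = cost, gamma = gamma)
}

#' Train-anchored [0,1] feature normalization
#'
#' Per-feature min-max map computed from the training rows only and applied
#' unchanged to any partition; values outside the training range extrapolate
#' beyond \[0, 1\] (no clipping). Constant features map to 0.
#'
#' @inheritParams normalize0255
#' @return matrix shaped like `apply_to`, attributes `"shift"` / `"scale"`.
#' @export
normalize01 <- function(train, apply_to = train) {
  .rangeNormalize(train, apply_to, hi = 1)
}

#' Fit the grid-searched SVM
#'
#' Radial-kernel SVM with hyperparameters selected by grid search maximizing
#' stratified inner-k-fold cross-validated performance on the training data
#' only (AUC for 2 classes, accuracy otherwise), then refit on the full
#' training partition. Features should already be [normalize01()]-mapped;
#' [fitSvmOnDataset()] does the whole protocol.
#'
#' @param x samples x features training matrix.
#' @param y factor of training labels (>= 2 classes).
#' @param grid a [svmGrid()].
#' @param inner_folds folds of the internal cross-validation (default 5).
#' @param seed integer seed (fold assignment and probability calibration).
#' @return object of class `"wvSvm"`: the refit `e1071::svm` model, `cost`,
#'   `gamma`, the inner-CV score table, and `class_levels`. Ties in the grid
#'   prefer the smallest cost, then the smallest gamma.
#' @export
fitSvm <- function(x, y, grid = svmGrid(), inner_folds = 5L, seed = 1L) {
  stopifnot(is.matrix(x))
  y <- droplevels(as.factor(y))
  if (nlevels(y) < 2L) stop("training partition needs >= 2 classes", call. = FALSE)
  inner_folds <- .checkCount(inner_folds, min = 2L, arg = "inner_folds")
  if (min(table(y)) < inner_folds)
    stop("too few samples in a class for stratified inner folds", call. = FALSE)
  fold <- stratifiedFolds(y, k = inner_folds, seed = seed)
  combos <- expand.grid(gamma = grid$gamma, cost = grid$cost,
                        KEEP.OUT.ATTRS = FALSE)
  cv <- vapply(seq_len(nrow(combos)), function(i) {
    .svmCvScore(x, y, fold, combos$cost[i], combos$gamma[i], seed)
  }, numeric(1))
  ## ties: smallest cost, then smallest gamma (combos is sorted that way
  ## within cost blocks; order rows explicitly to be safe)
  ord <- order(-cv, combos$cost, combos$gamma)
  best <- ord[1L]
  model <- .withSeed(seed,
    e1071::svm(x, y, kernel = "radial", cost = combos$cost[best],
               gamma = combos$gamma[best], scale = FALSE, probability = TRUE))
  structure(list(model = model, cost = combos$cost[best],
                 gamma = combos$gamma[best],
                 cv_scores = cbind(combos, score = cv),
                 class_levels = levels(y)),
            class = "wvSvm")
}

## Inner-CV score for one (cost, gamma): mean over folds of AUC (2-class,
## from signed decision values) or accuracy (multi-class).
.svmCvScore <- function(x, y, fold, cost, gamma, seed) {
  K <- nlevels(y)
  scores <- numeric(max(fold))
  for (f in seq_len(max(fold))) {
    tr <- fold != f
    if (length(unique(y[!tr])) < 1L || length(unique(y[tr])) < 2L) return(-Inf)
    m <- .withSeed(seed + f,
      e1071::svm(x[tr, , drop = FALSE], y[tr], kernel = "radial",
                 cost = cost, gamma = gamma, scale = FALSE))
    if (K == 2L) {
      pr <- predict(m, x[!tr, , drop = FALSE], decision.values = TRUE)
      dv <- attr(pr, "decision.values")
      ## decision value is positive for the class named first in the colname
      first <- strsplit(colnames(dv)[1L], "/", fixed = TRUE)[[1L]][1L]
      pos_score <- if (first == levels(y)[2L]) dv[, 1L] else -dv[, 1L]
      yt <- y[!tr]
      if (nlevels(droplevels(yt)) < 2L) { scores[f] <- NA_real_; next }
      scores[f] <- aucScore(pos_score, yt)
    } else {
      scores[f] <- mean(predict(m, x[!tr, , drop = FALSE]) == y[!tr])
    }
  }
  mean(scores, na.rm = TRUE)
}

#' @describeIn fitSvm score new samples; returns a samples x classes matrix
#'   (columns named by class level). For 2-class problems the scores are the
#'   signed decision values (+d for the second level, -d for the first), the
#'   same quantity the grid search ranks by; multi-class problems use the
#'   model's class-membership probabilities.
#' @param object a fitted `"wvSvm"`.
#' @param newdata samples x features matrix on the same normalization scale.
#' @export
svmScores <- function(object, newdata) {
  stopifnot(inherits(object, "wvSvm"), is.matrix(newdata))
  lv <- object$class_levels
  if (length(lv) == 2L) {
    pr <- predict(object$model, newdata, decision.values = TRUE)
    dv <- attr(pr, "decision.values")
    first <- strsplit(colnames(dv)[1L], "/", fixed = TRUE)[[1L]][1L]
    pos <- if (first == lv[2L]) dv[, 1L] else -dv[, 1L]
    out <- cbind(-pos, pos)
    colnames(out) <- lv
    rownames(out) <- rownames(newdata)
    return(out)
  }
  pr <- predict(object$model, newdata, probability = TRUE)
  p <- attr(pr, "probabilities")
  p[, lv, drop = FALSE]
}

#' Run the full SVM protocol on a dataset
#'
#' \[0,1\]-normalizes from the training rows only, grid-searches with inner
#' stratified cross-validation on the training partition, refits, and scores
#' both partitions.
#'
#' @param se dataset from [makeFeatureDataset()] / [generateSynthData()].
#' @inheritParams fitSvm
#' @return list with the `"wvSvm"` fit (`fit`), `train_scores`,
#'   `test_scores`, and the normalization parameters used.
#' @export
fitSvmOnDataset <- function(se, grid = svmGrid(), inner_folds = 5L, seed = 1L) {
  xtr <- featureMatrix(se, "train")
  xte <- featureMatrix(se, "test")
  ytr <- droplevels(sampleLabels(se, "train"))
  ntr <- normalize01(xtr)
  nte <- normalize01(xtr, xte)
  fit <- fitSvm(ntr, ytr, grid = grid, inner_folds = inner_folds, seed = seed)
  list(fit = fit,
       train_scores = svmScores(fit, ntr),
       test_scores = svmScores(fit, nte),
       norm_shift = attr(ntr, "shift"), norm_scale = attr(ntr, "scale"))
}
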