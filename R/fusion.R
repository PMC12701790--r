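## Score-level fusion: mean rule and z-normalized weighted mean rule.

#' z-normalize a score matrix
#'
#' Affine transform over all entries so that the matrix has mean 0 and
#' standard deviation 1 (statistics taken over the whole matrix; set
#' `per_class = TRUE` to normalize each column separately).
#'
#' @param S numeric score matrix with at least 2 distinct values.
#' @param per_class normalize each class column independently.
#' @return matrix of the same shape, mean 0 and sd 1 (overall or per column).
#' @export
zNormalizeScores <- function(S, per_class = FALSE) {
  stopifnot(is.matrix(S), all(is.finite(S)))
  if (per_class) {
    mu <- colMeans(S)
    sg <- apply(S, 2L, stats::sd)
    if (any(sg == 0)) stop("constant score column: sd undefined", call. = FALSE)
    return(sweep(sweep(S, 2L, mu, `-`), 2L, sg, `/`))
  }
  sg <- stats::sd(S)
  if (!is.finite(sg) || sg == 0)
    stop("constant score matrix: sd undefined", call. = FALSE)
  out <- (S - mean(S)) / sg
  dimnames(out) <- dimnames(S)
  out
}

#' Parse a fusion-rule expression
#'
#' Mini-grammar `w*name(+w*name)*`: terms separated by `+`, each an optional
#' nonnegative weight, `*`, and a score-source name; an omitted weight is 1.
#' `"2*svm+cnne"` therefore weights the SVM scores 2 and the CNN-ensemble
#' scores 1.
#'
#' @param rule character scalar.
#' @return named numeric vector of weights.
#' @examples
#' parseFusionRule("2*svm+cnne")
#' @export
parseFusionRule <- function(rule) {
  stopifnot(is.character(rule), length(rule) == 1L, nzchar(rule))
  terms <- strsplit(gsub("[[:space:]]", "", rule), "+", fixed = TRUE)[[1L]]
  if (!length(terms)) stop("empty fusion rule", call. = FALSE)
  w <- vapply(terms, function(t) {
    parts <- strsplit(t, "*", fixed = TRUE)[[1L]]
    if (length(parts) == 1L) 1 else {
      v <- suppressWarnings(as.numeric(parts[1L]))
      if (is.na(v) || v < 0 || length(parts) != 2L)
        stop(sprintf("malformed fusion term '%s'", t), call. = FALSE)
      v
    }
  }, numeric(1))
  names(w) <- vapply(terms, function(t) {
    parts <- strsplit(t, "*", fixed = TRUE)[[1L]]
    parts[length(parts)]
  }, character(1))
  if (all(w == 0)) stop("fusion weights must not all be zero", call. = FALSE)
  w
}

#' Fuse score matrices
#'
#' Weighted sum of shape-aligned score matrices. With `normalize = TRUE`
#' each component is z-normalized first (the convention for cross-family
#' fusions such as the weighted SVM + CNN-ensemble rules); the plain mean
#' rule over ensembles sharing a softmax scale skips normalization. Weights
#' default to 1 per component. Ranking metrics (AUC, argmax accuracy) are
#' invariant to overall positive scaling, so the weighted *sum* equals the
#' weighted mean for every downstream use.
#'
#' @param scores named list of samples x classes score matrices.
#' @param weights numeric vector of nonnegative weights (recycled names must
#'   match `scores`), or `NULL` for all-ones.
#' @param rule alternatively, a rule string for [parseFusionRule()]; its names
#'   select and weight entries of `scores`.
#' @param normalize z-normalize each component before combining.
#' @return fused score matrix.
#' @examples
#' a <- matrix(c(0.9, 0.1, 0.2, 0.8), 2, byrow = TRUE)
#' fuseScores(list(x = a, y = a))  # mean rule over identical sources
#' @export
fuseScores <- function(scores, weights = NULL, rule = NULL, normalize = FALSE) {
  stopifnot(is.list(scores), length(scores) >= 1L)
  if (!is.null(rule)) {
    w <- parseFusionRule(rule)
    missing <- setdiff(names(w), names(scores))
    if (length(missing))
      stop("rule names not found in scores: ", paste(missing, collapse = ", "),
           call. = FALSE)
    scores <- scores[names(w)]
    weights <- unname(w)
  }
  if (is.null(weights)) weights <- rep(1, length(scores))
  stopifnot(length(weights) == length(scores), all(weights >= 0))
  if (all(weights == 0)) stop("fusion weights must not all be zero", call. = FALSE)
  d <- dim(scores[[1L]])
  for (S in scores)
    if (!is.matrix(S) || !identical(dim(S), d))
      stop("score matrices are not shape-aligned", call. = FALSE)
  comps <- if (normalize) lapply(scores, zNormalizeScores) else scores
  out <- matrix(0, d[1L], d[2L], dimnames = dimnames(scores[[1L]]))
  for (i in seq_along(comps)) out <- out + weights[i] * comps[[i]]
  out
}
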