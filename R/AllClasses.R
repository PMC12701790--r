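#' @import methods
#' @importClassesFrom SummarizedExperiment SummarizedExperiment
NULL

#' WvEnsemble: a trained ensemble of image classifiers
#'
#' Container for an ensemble trained by [trainEnsemble()]. Each member holds
#' its feature permutation, normalization parameters, encoder draw (window
#' triple for the Wigner method) and fitted backbone model, so test data can
#' be pushed through the exact per-member pipeline at prediction time.
#'
#' @slot members list of fitted member pipelines (class `"wvMember"`).
#' @slot encoder list; the encoder configuration shared by all members
#'   (`method`, `quadrants`, `normalize_0_255`, `beta`, `target_size`).
#' @slot backboneName character; name of the backbone used.
#' @slot memberSeeds integer vector of the seeds of surviving members.
#' @slot droppedSeeds integer vector of seeds whose training diverged.
#' @slot classLevels character vector of class labels (column order of all
#'   score matrices).
#' @aliases WvEnsemble-class
#' @export
setClass("WvEnsemble",
  representation(members = "list", encoder = "list", backboneName = "character",
                 memberSeeds = "integer", droppedSeeds = "integer",
                 classLevels = "character"),
  validity = function(object) {
    msg <- NULL
    if (length(object@members) < 1L)
      msg <- c(msg, "ensemble must retain at least one converged member")
    if (length(object@memberSeeds) != length(object@members))
      msg <- c(msg, "one seed per surviving member required")
    if (length(object@classLevels) < 2L)
      msg <- c(msg, "at least two class levels required")
    if (is.null(msg)) TRUE else msg
  })

#' @describeIn WvEnsemble number of surviving members.
#' @param x,object a `WvEnsemble`.
#' @export
setMethod("length", "WvEnsemble", function(x) length(x@members))

#' @describeIn WvEnsemble compact description.
#' @export
setMethod("show", "WvEnsemble", function(object) {
  cat("WvEnsemble:", length(object@members), "member(s),",
      "encoder =", object@encoder$method,
      if (isTRUE(object@encoder$quadrants)) "(quadrant composition)" else "",
      "\n  backbone:", object@backboneName,
      "\n  classes:", paste(object@classLevels, collapse = ", "), "\n")
  if (length(object@droppedSeeds))
    cat("  dropped (non-convergent) member seeds:",
        paste(object@droppedSeeds, collapse = ", "), "\n")
})

#' Accessors for WvEnsemble
#'
#' @param object a [WvEnsemble-class] object.
#' @return `ensembleMembers()` the list of member pipelines; `memberSeeds()`
#'   their seeds; `classLevels()` the class labels.
#' @name WvEnsemble-accessors
NULL

#' @rdname WvEnsemble-accessors
#' @export
ensembleMembers <- function(object) object@members

#' @rdname WvEnsemble-accessors
#' @export
memberSeeds <- function(object) object@memberSeeds

#' @rdname WvEnsemble-accessors
#' @export
classLevels <- function(object) object@classLevels

#' Predict class scores
#'
#' @param object a fitted classifier object.
#' @param newdata new samples (samples x features matrix, or a
#'   `SummarizedExperiment` with a `"features"` assay).
#' @param ... passed to methods.
#' @return samples x classes score matrix.
#' @export
setGeneric("predictScores", function(object, newdata, ...)
  standardGeneric("predictScores"))
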