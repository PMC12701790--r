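## Ensemble of image classifiers: one feature permutation and one encoder
## draw per member, trained independently; class scores are averaged.

.defaultEncoderConfig <- function(method = "wigner", quadrants = FALSE,
                                  normalize_0_255 = TRUE, beta = 0.5,
                                  target_size = NULL) {
  list(method = method, quadrants = quadrants,
       normalize_0_255 = normalize_0_255, beta = beta, target_size = target_size)
}

#' Train one ensemble member
#'
#' Runs the per-member pipeline: draw a feature permutation from the member
#' seed, fit the 0-255 normalization on the (permuted) training rows when the
#' backbone path uses it, encode every training sample with one encoder draw,
#' and train the backbone, keeping per-epoch snapshots and the training-set
#' metric trace for best-epoch selection. Members whose training diverges
#' (non-finite loss) are reported as non-converged and dropped by
#' [trainEnsemble()] with a warning.
#'
#' @param train_x samples x features training matrix.
#' @param train_y factor of training labels (>= 2 classes).
#' @param member_seed integer seed for permutation, encoder draw and training.
#' @param encoder encoder configuration list (see [trainEnsemble()]).
#' @param backbone a backbone from [makeCnnBackbone()] (or any object obeying
#'   the backbone contract).
#' @return an object of class `"wvMember"`: `seed`, `permutation`,
#'   `norm` (0-255 parameters or `NULL`), `window_sizes`, `model`, `trace`,
#'   `best_epoch`, `train_scores`, `converged`.
#' @export
trainMember <- function(train_x, train_y, member_seed, encoder = .defaultEncoderConfig(),
                        backbone = makeCnnBackbone()) {
  stopifnot(is.matrix(train_x))
  train_y <- droplevels(as.factor(train_y))
  if (nlevels(train_y) < 2L)
    stop("training partition needs >= 2 classes", call. = FALSE)
  seeds <- .subSeeds(member_seed, 3L)  # permutation / encoder / training
  px <- permuteFeatures(train_x, seeds[1L])
  perm <- attr(px, "permutation")
  norm <- NULL
  if (isTRUE(encoder$normalize_0_255)) {
    px <- normalize0255(px)
    norm <- list(shift = attr(px, "shift"), scale = attr(px, "scale"))
  }
  imgs <- encodeBatch(px, method = encoder$method, seed = seeds[2L],
                      quadrants = isTRUE(encoder$quadrants),
                      target_size = encoder$target_size, beta = encoder$beta)
  model <- backbone$train(imgs, train_y, seeds[3L])
  if (!isTRUE(model$converged)) {
    return(structure(list(seed = member_seed, converged = FALSE),
                     class = "wvMember"))
  }
  structure(list(
    seed = member_seed, permutation = perm, norm = norm,
    window_sizes = attr(imgs, "window_sizes"), encoder = encoder,
    encoder_seed = seeds[2L], model = model, trace = model$trace,
    best_epoch = model$best_epoch,
    train_scores = backbone$predict(model, imgs),
    backbone = backbone, converged = TRUE), class = "wvMember")
}

#' Score new samples with one member
#'
#' Applies the member's recorded permutation, normalization parameters and
#' encoder draw to `newdata` and evaluates its best-epoch model.
#'
#' @param member a converged `"wvMember"`.
#' @param newdata samples x features matrix (original feature order).
#' @return samples x classes score matrix (post-softmax probabilities).
#' @export
memberScores <- function(member, newdata) {
  stopifnot(inherits(member, "wvMember"), isTRUE(member$converged),
            is.matrix(newdata))
  px <- newdata[, member$permutation, drop = FALSE]
  if (!is.null(member$norm))
    px <- sweep(sweep(px, 2L, member$norm$shift, `-`), 2L, member$norm$scale, `*`)
  enc <- member$encoder
  imgs <- encodeBatch(px, method = enc$method, seed = member$encoder_seed,
                      quadrants = isTRUE(enc$quadrants),
                      target_size = enc$target_size, beta = enc$beta)
  member$backbone$predict(member$model, imgs)
}

#' Train an ensemble of image classifiers
#'
#' Trains `n_members` independent members ([trainMember()]), each with its own
#' feature permutation and encoder draw, and collects the survivors into a
#' [WvEnsemble-class]. The reference configuration uses fifteen members;
#' desk-scale runs use fewer.
#'
#' @param se dataset from [makeFeatureDataset()] / [generateSynthData()].
#' @param n_members number of members to train.
#' @param method encoder method (`"wigner"`, `"reshape"`, `"cwt"`, `"dwt"`).
#' @param seed master seed; member seeds are derived from it.
#' @param backbone backbone specification (default [makeCnnBackbone()]).
#' @param quadrants use quadrant composition (long vectors).
#' @param normalize_0_255 fit the 0-255 train-anchored feature normalization
#'   (the SGD-momentum convention); set `FALSE` to feed raw features.
#' @param beta Kaiser shape parameter for the Wigner encoder.
#' @param target_size optional backbone input size (bilinear resize).
#' @return a [WvEnsemble-class] object.
#' @export
trainEnsemble <- function(se, n_members = 15L, method = "wigner", seed = 1L,
                          backbone = makeCnnBackbone(), quadrants = FALSE,
                          normalize_0_255 = TRUE, beta = 0.5, target_size = NULL) {
  n_members <- .checkCount(n_members, min = 1L, arg = "n_members")
  encoder <- .defaultEncoderConfig(method, quadrants, normalize_0_255, beta,
                                   target_size)
  xtr <- featureMatrix(se, "train")
  ytr <- droplevels(sampleLabels(se, "train"))
  member_seeds <- .subSeeds(seed, n_members)
  members <- lapply(member_seeds, function(s)
    trainMember(xtr, ytr, s, encoder = encoder, backbone = backbone))
  ok <- vapply(members, function(m) isTRUE(m$converged), logical(1))
  if (!all(ok))
    warning(sprintf("%d of %d members did not converge and were dropped",
                    sum(!ok), n_members))
  if (!any(ok))
    stop("no ensemble member converged", call. = FALSE)
  new("WvEnsemble", members = members[ok], encoder = encoder,
      backboneName = backbone$name, memberSeeds = as.integer(member_seeds[ok]),
      droppedSeeds = as.integer(member_seeds[!ok]),
      classLevels = levels(ytr))
}

#' Average member scores over an ensemble
#'
#' The ensemble output is the unweighted mean of the member score matrices --
#' linear in the members and invariant to their order.
#'
#' @param object a [WvEnsemble-class].
#' @param newdata samples x features matrix or a dataset
#'   `SummarizedExperiment` (its `"test"` partition is scored).
#' @param ... unused.
#' @return samples x classes score matrix.
#' @aliases predictScores,WvEnsemble,ANY-method
#' @export
setMethod("predictScores", "WvEnsemble", function(object, newdata, ...) {
  if (is(newdata, "SummarizedExperiment"))
    newdata <- featureMatrix(newdata, "test")
  per <- lapply(object@members, memberScores, newdata = newdata)
  Reduce(`+`, per) / length(per)
})
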