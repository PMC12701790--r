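## Small convolutional backbone, pure R (im2col + matrix multiply).
##
## Three 3x3 conv blocks (ReLU, 2x2 max pool) followed by global average
## pooling and a dense softmax head. Deliberately compact so an ensemble
## trains on one CPU in minutes; the backbone contract (see makeCnnBackbone)
## accepts any drop-in with the same train/predict surface.

#' Construct a small-CNN backbone specification
#'
#' Returns a backbone object satisfying the package's backbone contract: a
#' list with `name`, `train(images, labels, seed)` returning a fitted model
#' with per-epoch snapshots and a training-metric trace, and
#' `predict(model, images)` returning a samples x classes score matrix
#' (post-softmax probabilities).
#'
#' @param channels integer vector of feature-map counts for the three conv
#'   blocks.
#' @param learning_rate SGD step size. The default (0.01) suits a
#'   from-scratch small net; ImageNet-pretrained backbones conventionally use
#'   0.001.
#' @param momentum SGD momentum coefficient.
#' @param batch_size minibatch size (default 30).
#' @param epochs number of training epochs.
#' @param selection_metric metric maximized on the training set when picking
#'   the best epoch: `"auto"` (AUC for 2 classes, accuracy otherwise),
#'   `"accuracy"` or `"auc"`.
#' @return an object of class `"wvBackbone"`.
#' @export
makeCnnBackbone <- function(channels = c(4L, 8L, 16L), learning_rate = 0.01,
                            momentum = 0.9, batch_size = 30L, epochs = 8L,
                            selection_metric = c("auto", "accuracy", "auc")) {
  stopifnot(length(channels) == 3L, all(channels >= 1L),
            learning_rate > 0, epochs >= 1L, batch_size >= 1L)
  selection_metric <- match.arg(selection_metric)
  spec <- list(channels = as.integer(channels), learning_rate = learning_rate,
               momentum = momentum, batch_size = as.integer(batch_size),
               epochs = as.integer(epochs), selection_metric = selection_metric)
  structure(list(
    name = sprintf("cnn%s", paste(channels, collapse = "-")),
    spec = spec,
    train = function(images, labels, seed) .cnnTrain(images, labels, spec, seed),
    predict = function(model, images) .cnnPredict(model, images)
  ), class = "wvBackbone")
}

## ---- parameter initialisation -------------------------------------------

.cnnInitParams <- function(in_ch, channels, n_classes, feat_dim) {
  he <- function(fan_in, n_out) matrix(stats::rnorm(fan_in * n_out, 0, sqrt(2 / fan_in)),
                                       fan_in, n_out)
  chs <- c(in_ch, channels)
  p <- list()
  for (l in 1:3) {
    p[[paste0("W", l)]] <- he(9L * chs[l], chs[l + 1L])
    p[[paste0("b", l)]] <- numeric(chs[l + 1L])
  }
  ## dense head on the flattened final feature map: an energy ridge at a
  ## given frequency column is positional information, so no global pooling
  p$Wd <- he(feat_dim, n_classes) / sqrt(2)
  p$bd <- numeric(n_classes)
  p
}

## ---- im2col machinery ----------------------------------------------------

## Linear indices into a zero-padded (H+2, W+2, C, B) array for all 3x3
## patches; rows ordered (i fast, j, then batch), columns (di, dj, channel).
.im2colIndex <- function(H, W, C, B) {
  Hp <- H + 2L; Wp <- W + 2L
  ii <- rep(seq_len(H), times = W)
  jj <- rep(seq_len(W), each = H)
  pos <- matrix(0L, H * W, 9L * C)
  col <- 0L
  for (c in seq_len(C)) for (dj in 0:2) for (di in 0:2) {
    col <- col + 1L
    pos[, col] <- (ii + di) + (jj + dj - 1L) * Hp + (c - 1L) * Hp * Wp
  }
  if (B == 1L) return(pos)
  stride <- Hp * Wp * C
  idx <- matrix(0L, H * W * B, 9L * C)
  for (n in seq_len(B))
    idx[(n - 1L) * H * W + seq_len(H * W), ] <- pos + (n - 1L) * stride
  idx
}

.pad1 <- function(X) {
  d <- dim(X)
  P <- array(0, c(d[1L] + 2L, d[2L] + 2L, d[3L], d[4L]))
  P[2L:(d[1L] + 1L), 2L:(d[2L] + 1L), , ] <- X
  P
}

## Forward one conv block (3x3, pad 1, ReLU, 2x2 max pool). Returns what the
## backward pass needs.
.convForward <- function(X, Wt, b, idx) {
  d <- dim(X)  # H, W, C, B
  H <- d[1L]; B <- d[4L]
  P <- .pad1(X)
  cols <- matrix(P[idx], nrow = H * H * B)
  pre <- sweep(cols %*% Wt, 2L, b, `+`)
  F <- ncol(Wt)
  A <- aperm(array(pre, c(H, H, B, F)), c(1L, 2L, 4L, 3L))
  A[A < 0] <- 0
  pool <- .maxPool2(A)
  list(cols = cols, act = A, out = pool$out, which = pool$which, dimP = dim(P))
}

.maxPool2 <- function(A) {
  d <- dim(A)
  o1 <- seq(1L, d[1L], 2L); o2 <- seq(2L, d[1L], 2L)
  s <- list(A[o1, o1, , , drop = FALSE], A[o2, o1, , , drop = FALSE],
            A[o1, o2, , , drop = FALSE], A[o2, o2, , , drop = FALSE])
  out <- pmax(s[[1]], s[[2]], s[[3]], s[[4]])
  ## route gradient to the first sub-position attaining the max
  assigned <- array(FALSE, dim(out))
  which <- vector("list", 4L)
  for (k in 1:4) {
    which[[k]] <- (s[[k]] == out) & !assigned
    assigned <- assigned | which[[k]]
  }
  list(out = out, which = which)
}

.maxPoolBackward <- function(dOut, which, dimA) {
  dA <- array(0, dimA)
  o1 <- seq(1L, dimA[1L], 2L); o2 <- seq(2L, dimA[1L], 2L)
  slots <- list(list(o1, o1), list(o2, o1), list(o1, o2), list(o2, o2))
  for (k in 1:4) {
    g <- dOut * which[[k]]
    dA[slots[[k]][[1L]], slots[[k]][[2L]], , ] <-
      dA[slots[[k]][[1L]], slots[[k]][[2L]], , , drop = FALSE] + g
  }
  dA
}

.convBackward <- function(dPool, fw, Wt, idx, dimX) {
  H <- dimX[1L]; B <- dimX[4L]
  dA <- .maxPoolBackward(dPool, fw$which, dim(fw$act))
  dA[fw$act <= 0] <- 0
  F <- dim(dA)[3L]
  dPre <- matrix(aperm(dA, c(1L, 2L, 4L, 3L)), nrow = H * H * B, ncol = F)
  dW <- crossprod(fw$cols, dPre)
  db <- colSums(dPre)
  dCols <- tcrossprod(dPre, Wt)
  dP <- numeric(prod(fw$dimP))
  for (col in seq_len(ncol(idx)))
    dP[idx[, col]] <- dP[idx[, col]] + dCols[, col]
  dP <- array(dP, fw$dimP)
  dX <- dP[2L:(H + 1L), 2L:(H + 1L), , , drop = FALSE]
  list(dW = dW, db = db, dX = dX)
}

## Full forward pass; images (S, S, 3, B) already standardized.
.cnnForward <- function(X, params, idxs, keep = FALSE) {
  fws <- vector("list", 3L)
  cur <- X
  for (l in 1:3) {
    fws[[l]] <- .convForward(cur, params[[paste0("W", l)]],
                             params[[paste0("b", l)]], idxs[[l]])
    fws[[l]]$dimX <- dim(cur)
    cur <- fws[[l]]$out
  }
  d4 <- dim(cur)
  feat <- matrix(cur, prod(d4[1:3]), d4[4L])     # flatten to feat_dim x B
  scores <- sweep(crossprod(feat, params$Wd), 2L, params$bd, `+`)  # B x K
  probs <- .softmax(scores)
  if (keep) list(probs = probs, feat = feat, fws = fws, last = cur)
  else probs
}

.softmax <- function(S) {
  S <- S - apply(S, 1L, max)
  E <- exp(S)
  E / rowSums(E)
}

## ---- training ------------------------------------------------------------

.cnnTrain <- function(images, labels, spec, seed) {
  stopifnot(length(dim(images)) == 4L)
  d <- dim(images)
  S <- d[1L]
  if (d[2L] != S) stop("images must be square", call. = FALSE)
  ## three 2x2 pools need a side divisible by 8; zero-pad up when it is not
  Spad <- 8L * ((S + 7L) %/% 8L)
  if (Spad != S) images <- .padImagesTo(images, Spad)
  labels <- as.factor(labels)
  if (nlevels(labels) < 2L)
    stop("training partition must contain at least 2 classes", call. = FALSE)
  K <- nlevels(labels)
  y <- as.integer(labels)
  B <- d[4L]

  ## per-channel standardization from the training tensor
  mu <- apply(images, 3L, mean)
  sg <- apply(images, 3L, stats::sd)
  sg[sg == 0] <- 1
  X <- .standardizeImages(images, mu, sg)

  metric <- spec$selection_metric
  if (metric == "auto") metric <- if (K == 2L) "auc" else "accuracy"

  feat_dim <- (Spad %/% 8L)^2L * spec$channels[3L]
  .withSeed(seed, {
    params <- .cnnInitParams(3L, spec$channels, K, feat_dim)
    vel <- lapply(params, function(p) p * 0)
    bs <- min(spec$batch_size, B)
    idx_full <- .cnnIndexCache(Spad, spec$channels, bs)
    snapshots <- vector("list", spec$epochs)
    trace <- numeric(spec$epochs)
    diverged <- FALSE
    for (epoch in seq_len(spec$epochs)) {
      ord <- sample.int(B)
      for (start in seq(1L, B, by = bs)) {
        take <- ord[start:min(start + bs - 1L, B)]
        nb <- length(take)
        idxs <- if (nb == bs) idx_full else .cnnIndexCache(Spad, spec$channels, nb)
        g <- .cnnGradients(X[, , , take, drop = FALSE], y[take], K, params, idxs)
        if (!all(vapply(g, function(m) all(is.finite(m)), logical(1)))) {
          diverged <- TRUE
          break
        }
        for (nm in names(params)) {
          vel[[nm]] <- spec$momentum * vel[[nm]] - spec$learning_rate * g[[nm]]
          params[[nm]] <- params[[nm]] + vel[[nm]]
        }
      }
      if (diverged) break
      snapshots[[epoch]] <- params
      probs <- .cnnForwardAll(X, params, spec$channels)
      trace[epoch] <- .trainMetric(probs, y, K, metric)
    }
    if (diverged && is.null(snapshots[[1L]]))
      return(structure(list(converged = FALSE), class = "wvCnnModel"))
    done <- which(!vapply(snapshots, is.null, logical(1)))
    structure(list(
      converged = TRUE, snapshots = snapshots[done], trace = trace[done],
      class_levels = levels(labels), channels = spec$channels,
      input_size = S, pad_to = Spad, mu = mu, sigma = sg, metric = metric,
      best_epoch = selectBestEpoch(trace[done])
    ), class = "wvCnnModel")
  })
}

.standardizeImages <- function(images, mu, sg) {
  X <- images
  for (c in 1:3) X[, , c, ] <- (X[, , c, ] - mu[c]) / sg[c]
  X
}

.cnnIndexCache <- function(S, channels, B) {
  sizes <- c(S, S %/% 2L, S %/% 4L)
  chs <- c(3L, channels[1L], channels[2L])
  lapply(1:3, function(l) .im2colIndex(sizes[l], sizes[l], chs[l], B))
}

.cnnGradients <- function(Xb, yb, K, params, idxs) {
  fw <- .cnnForward(Xb, params, idxs, keep = TRUE)
  B <- length(yb)
  dScores <- fw$probs
  dScores[cbind(seq_len(B), yb)] <- dScores[cbind(seq_len(B), yb)] - 1
  dScores <- dScores / B
  g <- list(Wd = fw$feat %*% dScores, bd = colSums(dScores))
  dFeat <- params$Wd %*% t(dScores)               # feat_dim x B
  dCur <- array(dFeat, dim(fw$last))
  for (l in 3:1) {
    bk <- .convBackward(dCur, fw$fws[[l]], params[[paste0("W", l)]],
                        idxs[[l]], fw$fws[[l]]$dimX)
    g[[paste0("W", l)]] <- bk$dW
    g[[paste0("b", l)]] <- bk$db
    dCur <- bk$dX
  }
  g
}

## Forward a full (possibly large) tensor in chunks.
.cnnForwardAll <- function(X, params, channels, chunk = 64L) {
  B <- dim(X)[4L]
  S <- dim(X)[1L]
  out <- NULL
  for (start in seq(1L, B, by = chunk)) {
    take <- start:min(start + chunk - 1L, B)
    idxs <- .cnnIndexCache(S, channels, length(take))
    p <- .cnnForward(X[, , , take, drop = FALSE], params, idxs)
    out <- rbind(out, p)
  }
  out
}

.trainMetric <- function(probs, y, K, metric) {
  if (metric == "auc" && K == 2L)
    return(aucScore(probs[, 2L], y == 2L))
  mean(max.col(probs, ties.method = "first") == y)
}

.padImagesTo <- function(images, Spad) {
  d <- dim(images)
  out <- array(0, c(Spad, Spad, d[3L], d[4L]))
  out[seq_len(d[1L]), seq_len(d[2L]), , ] <- images
  out
}

.cnnPredict <- function(model, images) {
  stopifnot(inherits(model, "wvCnnModel"))
  if (!isTRUE(model$converged)) stop("model did not converge", call. = FALSE)
  if (dim(images)[1L] != model$input_size)
    stop("image size does not match the trained input size", call. = FALSE)
  if (model$pad_to != model$input_size)
    images <- .padImagesTo(images, model$pad_to)
  params <- model$snapshots[[model$best_epoch]]
  X <- .standardizeImages(images, model$mu, model$sigma)
  probs <- .cnnForwardAll(X, params, model$channels)
  colnames(probs) <- model$class_levels
  probs
}

#' Pick the best epoch from a training-metric trace
#'
#' Returns the index of the epoch maximizing the training-set selection
#' metric; ties are broken in favour of the earliest epoch.
#'
#' @param trace numeric vector of per-epoch training metrics.
#' @return integer epoch index.
#' @examples
#' selectBestEpoch(c(0.8, 0.95, 0.90))  # 2
#' @export
selectBestEpoch <- function(trace) {
  if (length(trace) == 0L) stop("empty training trace", call. = FALSE)
  which.max(trace)  # which.max returns the first maximum
}
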