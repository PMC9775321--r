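# Training: three forward passes per step (raw, attention-cropped,
# attention-dropped), cross-entropy on each, plus a center-style attention
# regularization on the raw-pass part features. Part-feature centers are
# non-trainable state updated by a moving average after the forward pass.

#' Attention regularization loss
#'
#' Sum over parts of the squared Euclidean distance between each
#' part-feature vector and its moving-average center; zero exactly when
#' every part feature sits on its center.
#'
#' @param f An N x M part-feature matrix (rows are part features), or a
#'   list of N length-M vectors.
#' @param centers An N x M matrix of part centers.
#' @return Nonnegative scalar.
#' @export
attentionRegLoss <- function(f, centers) {
  if (is.list(f)) f <- do.call(rbind, f)
  if (!all(dim(f) == dim(centers)))
    stop("part features and centers have mismatched shapes", call. = FALSE)
  sum((f - centers)^2)
}

#' Moving-average update of the part-feature centers
#'
#' Applies `c <- c + beta * (f - c)` per part: a convex step of the centers
#' toward the current batch-mean part features. No gradient flows through
#' the centers; they are plain state.
#'
#' @param centers Current N x M center matrix.
#' @param f Batch-mean N x M part-feature matrix.
#' @param beta Update rate in (0, 1].
#' @return The updated N x M center matrix.
#' @export
updateCenters <- function(centers, f, beta = 0.05) {
  if (beta <= 0 || beta > 1) stop("beta must lie in (0, 1]", call. = FALSE)
  if (!all(dim(f) == dim(centers)))
    stop("part features and centers have mismatched shapes", call. = FALSE)
  centers + beta * (f - centers)
}

initOptimizer <- function(model) zeroLike(model@params)

defaultTrainConfig <- function() {
  list(lr = 0.001, momentum = 0.9, lambda = 1, beta = 0.05,
       thetaC = 0.5, thetaD = 0.5, augment = TRUE, sampleThresholds = FALSE,
       batchSize = 16L, epochs = 10L, cosineDecay = TRUE)
}

labelIndex <- function(labels, classes) {
  idx <- match(as.character(labels), classes)
  if (anyNA(idx))
    stop("labels contain classes unknown to the model", call. = FALSE)
  idx
}

crossEntropy <- function(probs, yIdx) {
  -mean(log(pmax(probs[cbind(yIdx, seq_along(yIdx))], 1e-12)))
}

#' One optimization step over a mini-batch
#'
#' Runs the raw forward pass, derives the attention-guided crop and drop
#' batches from the raw-pass attention maps (mask construction is
#' non-differentiable and detached), forwards both augmented batches, and
#' takes one momentum-SGD step on
#' `(ceRaw + ceCrop + ceDrop)/3 + lambda * LA`, where the attention
#' regularization `LA` is the summed squared distance between the raw-pass
#' L2-normalized part features and their moving-average centers (crop/drop
#' passes contribute cross-entropy only). Centers are then updated from the
#' raw-pass batch mean of the normalized part features.
#'
#' @param model A [WSModel-class].
#' @param images List of image matrices for the batch.
#' @param labels Batch labels (match the model's classes).
#' @param opt Optimizer state from `initOptimizer` (momentum velocities).
#' @param lr,momentum SGD step size and momentum.
#' @param lambda Weight of the attention regularization loss.
#' @param beta Center update rate in (0, 1].
#' @param thetaC,thetaD Crop/drop thresholds.
#' @param augment If `FALSE`, only the raw cross-entropy (weight 1) is
#'   used; with augmentation each cross-entropy term gets weight 1/3.
#' @param stepSeed Integer seed for the attention-map selection.
#' @return A list with the updated `model`, `opt`, and a `losses` list
#'   (`ce_raw`, `ce_crop`, `ce_drop`, `l_attention`, `total`).
#' @export
trainStep <- function(model, images, labels, opt, lr = 0.001, momentum = 0.9,
                      lambda = 1, beta = 0.05, thetaC = 0.5, thetaD = 0.5,
                      augment = TRUE, stepSeed = 1L) {
  if (length(images) == 0L) stop("empty batch", call. = FALSE)
  cfg <- model@config
  params <- model@params
  state <- model@state
  yIdx <- labelIndex(labels, cfg$classes)
  B <- length(images)
  Y <- matrix(0, length(cfg$classes), B)
  Y[cbind(yIdx, seq_len(B))] <- 1
  wCE <- if (augment) 1 / 3 else 1

  x <- toBatch(model, images)
  fwd <- modelForward(params, state, cfg, x, train = TRUE)
  state <- fwd$state
  ceRaw <- crossEntropy(fwd$probs, yIdx)
  # Attention regularization on the L2-normalized part features (the same
  # representation the classifier consumes). Regularizing the raw pooled
  # features instead admits the degenerate solution of shrinking all
  # attention to zero; the normalized form penalizes only the direction of
  # each part feature relative to its moving center.
  la <- 0
  dUextra <- NULL
  Uarr <- array(fwd$cache$U, dim(fwd$P))
  if (lambda > 0) {
    diffU <- sweep(Uarr, c(1L, 2L), model@centers)
    la <- sum(diffU^2) / B
    dUextra <- 2 * lambda * matrix(diffU, ncol = B) / B
  }
  bk <- modelBackward(params, cfg, fwd, (fwd$probs - Y) * wCE / B,
                      dUextra = dUextra)
  grads <- bk$grads

  ceCrop <- NA_real_
  ceDrop <- NA_real_
  if (augment) {
    Alist <- lapply(seq_len(B), function(b)
      array(fwd$A[, , , b], dim(fwd$A)[1:3]))
    imgs <- lapply(images, imageToUnit)
    aug <- augmentBatch(imgs, Alist, thetaC, thetaD, seed = stepSeed,
                        outSize = cfg$inputSize)
    for (kind in c("cropped", "dropped")) {
      xa <- toBatch(model, aug[[kind]])
      fa <- modelForward(params, state, cfg, xa, train = TRUE)
      state <- fa$state
      ce <- crossEntropy(fa$probs, yIdx)
      if (kind == "cropped") ceCrop <- ce else ceDrop <- ce
      ba <- modelBackward(params, cfg, fa, (fa$probs - Y) / 3 / B, NULL)
      grads <- addTrees(grads, ba$grads)
    }
  }

  total <- if (augment) (ceRaw + ceCrop + ceDrop) / 3 + lambda * la
           else ceRaw + lambda * la
  if (!is.finite(total)) {
    stop(sprintf(paste0("non-finite training loss (ce_raw=%.4g, la=%.4g); ",
                        "|F|=%.4g |A|=%.4g |P|=%.4g"),
                 ceRaw, la, sqrt(mean(fwd$F^2)), sqrt(mean(fwd$A^2)),
                 sqrt(mean(fwd$P^2))), call. = FALSE)
  }

  opt <- pmapLeaves(function(v, g) momentum * v - lr * g, opt, grads)
  params <- addTrees(params, opt)
  centers <- updateCenters(model@centers, apply(Uarr, c(1L, 2L), mean), beta)
  model@params <- params
  model@state <- state
  model@centers <- centers
  list(model = model, opt = opt,
       losses = list(ce_raw = ceRaw, ce_crop = ceCrop, ce_drop = ceDrop,
                     l_attention = la, total = total))
}

#' Class probabilities for a set of images (evaluation mode)
#'
#' @param model A [WSModel-class].
#' @param images List of image matrices (or a [SliceDataset-class]).
#' @param batchSize Evaluation batch size.
#' @return An n x K matrix of class probabilities (columns named by class).
#' @export
predictProbs <- function(model, images, batchSize = 32L) {
  if (methods::is(images, "SliceDataset")) images <- images@images
  n <- length(images)
  K <- length(model@config$classes)
  out <- matrix(NA_real_, n, K, dimnames = list(NULL, model@config$classes))
  i <- 1L
  while (i <= n) {
    j <- min(n, i + batchSize - 1L)
    x <- toBatch(model, images[i:j])
    fwd <- modelForward(model@params, model@state, model@config, x,
                        train = FALSE)
    out[i:j, ] <- t(fwd$probs)
    i <- j + 1L
  }
  out
}

#' Decide a class label from probabilities
#'
#' Argmax with ties broken toward the first (negative) class — the
#' conservative choice for a screening metric.
#'
#' @param probs Named probability vector or n x K matrix.
#' @return Character label(s).
#' @export
decideLabel <- function(probs) {
  if (is.matrix(probs)) {
    cls <- colnames(probs)
    apply(probs, 1L, function(p) cls[which.max(p)])
  } else {
    names(probs)[which.max(probs)]
  }
}

#' Train the model with per-epoch validation
#'
#' Epoch loop over seeded mini-batches with cosine learning-rate decay;
#' each step follows [trainStep()]. The checkpoint with the best validation
#' accuracy (earliest epoch on ties) is retained. Fully reproducible given
#' the seed.
#'
#' @param model A freshly built or partially trained [WSModel-class].
#' @param trainData,valData [SliceDataset-class] objects (or lists with
#'   `images` and `labels`).
#' @param epochs Number of epochs (0 returns the initial model and an empty
#'   log).
#' @param batchSize Mini-batch size.
#' @param lr,momentum SGD settings; `lr` is the initial step size.
#' @param lambda,beta,thetaC,thetaD,augment As in [trainStep()].
#' @param cosineDecay Cosine-decay the learning rate over epochs.
#' @param seed Master seed; shuffling and augmentation draw from derived
#'   substreams.
#' @param verbose Print one line per epoch.
#' @return A list with `model` (best-on-validation), `finalModel`, `log`
#'   (one row per epoch), and `bestEpoch`.
#' @export
fitModel <- function(model, trainData, valData = NULL, epochs = 10L,
                     batchSize = 16L, lr = 0.001, momentum = 0.9, lambda = 1,
                     beta = 0.05, thetaC = 0.5, thetaD = 0.5, augment = TRUE,
                     cosineDecay = TRUE, seed = 1L, verbose = FALSE) {
  tr <- asImageSet(trainData)
  if (length(tr$images) == 0L) stop("empty training set", call. = FALSE)
  va <- if (!is.null(valData)) asImageSet(valData)
  log <- data.frame()
  opt <- initOptimizer(model)
  best <- model
  bestAcc <- -Inf
  bestEpoch <- 0L
  n <- length(tr$images)
  for (e in seq_len(epochs)) {
    lrE <- if (cosineDecay && epochs > 1L)
      lr * 0.5 * (1 + cos(pi * (e - 1) / epochs)) else lr
    ord <- withSeed(subSeed(seed, "epoch") + e, sample.int(n))
    sums <- c(ce_raw = 0, ce_crop = 0, ce_drop = 0, l_attention = 0, total = 0)
    nb <- 0L
    i <- 1L
    while (i <= n) {
      j <- min(n, i + batchSize - 1L)
      idx <- ord[i:j]
      stepSeed <- (subSeed(seed, "augment") + e * 10007L + nb) %% 2147483629L
      st <- trainStep(model, tr$images[idx], tr$labels[idx], opt,
                      lr = lrE, momentum = momentum, lambda = lambda,
                      beta = beta, thetaC = thetaC, thetaD = thetaD,
                      augment = augment, stepSeed = stepSeed)
      model <- st$model
      opt <- st$opt
      ls <- unlist(st$losses)
      ls[is.na(ls)] <- 0
      sums <- sums + ls
      nb <- nb + 1L
      i <- j + 1L
    }
    valAcc <- NA_real_
    if (!is.null(va)) {
      pr <- predictProbs(model, va$images)
      valAcc <- mean(decideLabel(pr) == as.character(va$labels))
      if (valAcc > bestAcc) {
        bestAcc <- valAcc
        best <- model
        bestEpoch <- e
      }
    } else {
      best <- model
      bestEpoch <- e
    }
    row <- data.frame(epoch = e, lr = lrE, t(sums / nb), val_accuracy = valAcc)
    log <- rbind(log, row)
    if (verbose)
      message(sprintf("epoch %d: loss %.4f, val acc %s", e, row$total,
                      ifelse(is.na(valAcc), "-", sprintf("%.3f", valAcc))))
  }
  list(model = best, finalModel = model, log = log, bestEpoch = bestEpoch)
}

asImageSet <- function(x) {
  if (methods::is(x, "SliceDataset"))
    list(images = x@images, labels = x@labels)
  else if (is.list(x) && !is.null(x$images))
    list(images = x$images, labels = x$labels)
  else stop("expected a SliceDataset or list(images, labels)", call. = FALSE)
}

# ---- checkpointing ----------------------------------------------------

configHash <- function(cfg) {
  bytes <- as.integer(serialize(cfg, NULL, version = 2L))
  h <- 2166136261
  for (b in bytes) {
    h <- bitwXor(as.integer(h %% 2^31), b)  # fold to keep integer arithmetic
    h <- (h * 16777619) %% 2^32
  }
  sprintf("%08x", as.integer(h %% 2^31))
}

#' Save a model checkpoint
#'
#' Stores all parameters, batch-norm state, centers, the configuration and
#' a configuration hash.
#'
#' @param model A [WSModel-class].
#' @param path Output file path.
#' @export
writeModel <- function(model, path) {
  saveRDS(list(config = model@config, params = model@params,
               state = model@state, centers = model@centers,
               hash = configHash(model@config)), path)
  invisible(path)
}

#' Load a model checkpoint
#'
#' @param path Checkpoint written by [writeModel()].
#' @return A [WSModel-class].
#' @export
readModel <- function(path) {
  ck <- readRDS(path)
  if (!identical(ck$hash, configHash(ck$config)))
    stop("checkpoint configuration hash mismatch", call. = FALSE)
  methods::new("WSModel", config = ck$config, params = ck$params,
               state = ck$state, centers = ck$centers)
}
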