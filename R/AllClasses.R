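#' @import methods
NULL

#' Specification of a synthetic slice dataset
#'
#' Describes the generator for grayscale brain-like slices in which the
#' positive class carries a localized disk-shaped intensity perturbation (a
#' planted "lesion") at a class-consistent, jittered location and the
#' negative class does not. Images are quantized to `grayLevels` levels.
#'
#' @slot imageSize Integer height and width of each slice.
#' @slot nPerClass Number of slices generated per class.
#' @slot lesionRadius Lesion disk radius in pixels.
#' @slot lesionContrast Intensity offset of the lesion, in [0, 1].
#' @slot noiseSd Standard deviation of the additive Gaussian pixel noise
#'   (intensity units, before clipping to [0, 1]).
#' @slot seed Integer seed; the same spec yields a bitwise-identical dataset.
#' @slot grayLevels Number of quantization levels (default 256).
#' @export
setClass("SyntheticSpec",
  representation(imageSize = "integer", nPerClass = "integer",
                 lesionRadius = "numeric", lesionContrast = "numeric",
                 noiseSd = "numeric", seed = "integer",
                 grayLevels = "integer"))

setValidity("SyntheticSpec", function(object) {
  sz <- object@imageSize
  if (length(sz) != 2L || any(sz < 4L))
    return("imageSize must be two integers >= 4")
  if (object@noiseSd < 0) return("noiseSd must be >= 0")
  if (object@lesionContrast < 0 || object@lesionContrast > 1)
    return("lesionContrast must lie in [0, 1]")
  # lesion (with its +/-10% location jitter around the off-center anchor)
  # must fit inside the image
  if (object@lesionRadius + 0.1 * max(sz) > 0.4 * min(sz))
    return("lesion (radius plus location jitter) does not fit inside the image")
  if (object@grayLevels < 2L) return("grayLevels must be >= 2")
  TRUE
})

#' A labeled set of grayscale slices
#'
#' Container for quantized grayscale slices (integer matrices with values in
#' `[0, grayLevels - 1]`), their binary class labels, and — for synthetic
#' data — the planted lesion centers used as ground truth.
#'
#' @slot images List of integer matrices, one per slice.
#' @slot labels Factor of per-slice class labels.
#' @slot sourceIds Character identifiers (volume + slice index, or synthetic id).
#' @slot lesionCenters Numeric n x 2 matrix of planted lesion centers
#'   (row, col; `NA` for slices without a lesion).
#' @slot grayLevels Integer number of gray levels.
#' @export
setClass("SliceDataset",
  representation(images = "list", labels = "factor", sourceIds = "character",
                 lesionCenters = "matrix", grayLevels = "integer"))

setValidity("SliceDataset", function(object) {
  n <- length(object@images)
  if (length(object@labels) != n) return("labels length != number of images")
  if (length(object@sourceIds) != n) return("sourceIds length != number of images")
  if (nrow(object@lesionCenters) != n) return("lesionCenters rows != number of images")
  TRUE
})

#' Stratified train/validation/test partition
#'
#' @slot assignments Data frame with columns `id`, `class`, `partition`
#'   (one of `"train"`, `"val"`, `"test"`).
#' @export
setClass("DatasetSplit", representation(assignments = "data.frame"))

setValidity("DatasetSplit", function(object) {
  a <- object@assignments
  if (!all(c("id", "class", "partition") %in% names(a)))
    return("assignments needs columns id, class, partition")
  if (anyDuplicated(a$id)) return("ids assigned to more than one partition")
  if (!all(a$partition %in% c("train", "val", "test")))
    return("partition must be train/val/test")
  TRUE
})

#' Attention-gated residual classification model
#'
#' Holds the parameters and configuration of the full pipeline: the residual
#' backbone with channel+spatial attention gates in every bottleneck block,
#' the 1x1-convolution attention head, the linear classifier over the
#' bilinear-attention-pooled part-feature matrix, and the moving-average
#' part-feature centers used by the attention regularization loss.
#'
#' @slot config List of architecture and preprocessing settings.
#' @slot params List of trainable parameter arrays.
#' @slot state List of non-trainable state (batch-norm running moments).
#' @slot centers N x M matrix of part-feature centers (initialized to zero).
#' @export
setClass("WSModel",
  representation(config = "list", params = "list", state = "list",
                 centers = "matrix"))

#' Confusion-matrix tallies
#'
#' @slot tp,fp,tn,fn Nonnegative integer counts; the positive class is the
#'   disease class (AD in the motivating application).
#' @export
setClass("ConfusionCounts",
  representation(tp = "integer", fp = "integer", tn = "integer", fn = "integer"))

setValidity("ConfusionCounts", function(object) {
  v <- c(object@tp, object@fp, object@tn, object@fn)
  if (any(v < 0L)) return("counts must be nonnegative")
  TRUE
})

# ---- show methods -----------------------------------------------------

setMethod("show", "SyntheticSpec", function(object) {
  cat(sprintf("SyntheticSpec: %dx%d slices, %d per class\n",
              object@imageSize[1L], object@imageSize[2L], object@nPerClass))
  cat(sprintf("  lesion: radius %.1f px, contrast %.2f; noise sd %.3f; seed %d; %d gray levels\n",
              object@lesionRadius, object@lesionContrast, object@noiseSd,
              object@seed, object@grayLevels))
})

setMethod("show", "SliceDataset", function(object) {
  cat(sprintf("SliceDataset: %d slices (%s), %d gray levels\n",
              length(object@images),
              paste(sprintf("%s=%d", levels(object@labels),
                            tabulate(object@labels)), collapse = ", "),
              object@grayLevels))
})

setMethod("show", "DatasetSplit", function(object) {
  tab <- table(object@assignments$class, object@assignments$partition)
  cat("DatasetSplit:\n")
  print(tab)
})

setMethod("show", "WSModel", function(object) {
  cfg <- object@config
  cat(sprintf("WSModel '%s': input %dx%dx%d, %d attention maps, %d feature channels\n",
              cfg$arch, cfg$inputSize[1L], cfg$inputSize[2L], cfg$inChannels,
              cfg$nMaps, cfg$featureChannels))
  cat(sprintf("  %d attention-gated bottleneck blocks; %s parameters\n",
              length(cfg$blocks),
              format(countParams(object), big.mark = ",")))
})

setMethod("show", "ConfusionCounts", function(object) {
  cat(sprintf("ConfusionCounts: TP=%d FP=%d TN=%d FN=%d (n=%d)\n",
              object@tp, object@fp, object@tn, object@fn,
              object@tp + object@fp + object@tn + object@fn))
})

# ---- accessors --------------------------------------------------------

#' @rdname DatasetSplit-class
#' @param x A `DatasetSplit`.
#' @export
trainIds <- function(x) x@assignments$id[x@assignments$partition == "train"]

#' @rdname DatasetSplit-class
#' @export
valIds <- function(x) x@assignments$id[x@assignments$partition == "val"]

#' @rdname DatasetSplit-class
#' @export
testIds <- function(x) x@assignments$id[x@assignments$partition == "test"]

#' @rdname DatasetSplit-class
#' @export
splitTable <- function(x) x@assignments

#' @rdname WSModel-class
#' @param model A `WSModel`.
#' @export
modelConfig <- function(model) model@config

#' @rdname WSModel-class
#' @export
nAttentionMaps <- function(model) model@config$nMaps

#' @rdname WSModel-class
#' @export
featureCenters <- function(model) model@centers

#' @rdname WSModel-class
#' @export
countParams <- function(model) {
  n <- 0L
  rapply(model@params, function(a) n <<- n + length(a), how = "unlist")
  n
}

#' @rdname SliceDataset-class
#' @param x A `SliceDataset`.
#' @export
sliceImages <- function(x) x@images

#' @rdname SliceDataset-class
#' @export
sliceLabels <- function(x) x@labels

#' @rdname SliceDataset-class
#' @export
lesionCenters <- function(x) x@lesionCenters

#' @rdname ConfusionCounts-class
#' @param cc A `ConfusionCounts`.
#' @export
asCounts <- function(cc) c(TP = cc@tp, FP = cc@fp, TN = cc@tn, FN = cc@fn)
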