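# Two-pass test-time inference and confusion-matrix metrics. The coarse
# probability comes from the raw image; the fine probability from a second
# forward pass on the attention-guided crop (the summed attention maps,
# normalized and thresholded, define the crop box); the final prediction
# averages the two.

#' Coarse classification probability of one image
#'
#' Raw image through backbone, attention head, bilinear attention pooling
#' and the linear classifier (evaluation mode; deterministic).
#'
#' @param model A trained [WSModel-class].
#' @param image An H x W matrix.
#' @return Named probability vector over the model's classes.
#' @export
predictCoarse <- function(model, image) {
  pr <- predictProbs(model, list(image))
  stats::setNames(as.vector(pr[1L, ]), colnames(pr))
}

#' Fine classification probability of one image
#'
#' Sums the attention maps over parts, min-max normalizes the sum, builds a
#' crop box at `thetaTest`, crops and bilinearly enlarges the original
#' image, and classifies the crop. A flat attention map falls back to the
#' full-image box, making the fine probability equal the coarse one.
#'
#' @param model A trained [WSModel-class].
#' @param image An H x W matrix.
#' @param thetaTest Crop threshold on the normalized summed attention map
#'   (default 0.1).
#' @return Named probability vector; the crop box used is attached as
#'   attribute `"box"`.
#' @export
predictFine <- function(model, image, thetaTest = 0.1) {
  A <- attentionMaps(model, image)
  Asum <- apply(A, c(1L, 2L), sum)
  Anorm <- normalizeAttention(Asum)
  cm <- cropMask(Anorm, thetaTest, warn = FALSE)
  img <- imageToUnit(image)
  crop <- applyCrop(img, cm$box, model@config$inputSize, gridSize = dim(Anorm))
  pf <- predictCoarse(model, crop)
  attr(pf, "box") <- cm$box
  pf
}

#' Fuse coarse and fine probabilities
#'
#' The final probability is the arithmetic mean of the coarse and fine
#' class probabilities; normalization is preserved and the operation is
#' symmetric.
#'
#' @param pc,pf Probability vectors of equal length.
#' @return The averaged probability vector.
#' @export
fuseProbabilities <- function(pc, pf) {
  if (length(pc) != length(pf))
    stop("probability vectors have different lengths", call. = FALSE)
  (pc + pf) / 2
}

#' Fused two-pass prediction for one image
#'
#' @inheritParams predictFine
#' @return Named fused probability vector.
#' @export
predictFused <- function(model, image, thetaTest = 0.1) {
  pc <- predictCoarse(model, image)
  pf <- predictFine(model, image, thetaTest)
  fuseProbabilities(pc, stats::setNames(as.vector(pf), names(pc)))
}

#' Confusion-matrix tallies
#'
#' @param labels True labels.
#' @param predictions Predicted labels (same length).
#' @param positive Name of the positive (disease) class; everything else
#'   counts as negative.
#' @return A [ConfusionCounts-class].
#' @export
confusionCounts <- function(labels, predictions, positive = "positive") {
  if (length(labels) == 0L) stop("no samples to tally", call. = FALSE)
  if (length(labels) != length(predictions))
    stop("labels and predictions differ in length", call. = FALSE)
  lab <- as.character(labels) == positive
  pred <- as.character(predictions) == positive
  methods::new("ConfusionCounts",
               tp = sum(lab & pred), fp = sum(!lab & pred),
               tn = sum(!lab & !pred), fn = sum(lab & !pred))
}

#' Sensitivity, specificity, precision, accuracy and F1 score
#'
#' Computes the five standard screening metrics from confusion counts:
#' sensitivity TP/(TP+FN), specificity TN/(FP+TN), precision TP/(TP+FP),
#' accuracy (TP+TN)/n, and F1 = 2TP/(2TP+FP+FN). A metric whose
#' denominator is zero is reported as `NA` and flagged in the
#' `"undefined"` attribute rather than silently set to 0.
#'
#' @param cc A [ConfusionCounts-class].
#' @param percent Report values as percentages rounded to 2 decimals (the
#'   usual table format) instead of proportions.
#' @return Named numeric vector with attribute `"undefined"` naming any
#'   undefined metrics.
#' @export
classificationMetrics <- function(cc, percent = FALSE) {
  tp <- cc@tp; fp <- cc@fp; tn <- cc@tn; fn <- cc@fn
  safe <- function(num, den) if (den == 0L) NA_real_ else num / den
  m <- c(sensitivity = safe(tp, tp + fn),
         specificity = safe(tn, fp + tn),
         precision = safe(tp, tp + fp),
         accuracy = safe(tp + tn, tp + fp + tn + fn),
         f1 = safe(2 * tp, 2 * tp + fp + fn))
  und <- names(m)[is.na(m)]
  if (percent) m <- round(m * 100, 2L)
  if (length(und)) attr(m, "undefined") <- und
  m
}
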