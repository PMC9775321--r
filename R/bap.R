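# Bilinear attention pooling: attention maps are generated from the feature
# stack by a 1x1 convolution with a nonnegativity activation; each map
# gates the features element-wise and the gated stack is global-average
# pooled into one part-feature row, giving the N x M part-feature matrix
# consumed by the linear classifier.

#' Generate attention maps from feature maps
#'
#' Applies a 1x1 convolution from the M feature channels to `n_maps`
#' attention channels followed by a ReLU, so every attention value is
#' nonnegative and the spatial dimensions are preserved.
#'
#' @param F An H x W x M feature array.
#' @param W Either a 1 x 1 x M x N kernel array or an M x N matrix of
#'   per-channel weights.
#' @param b Optional bias vector of length N.
#' @return An H x W x N nonnegative attention array.
#' @export
attentionHead <- function(F, W, b = NULL) {
  F <- as4d(F)
  if (is.matrix(W)) W <- array(W, c(1L, 1L, nrow(W), ncol(W)))
  if (dim(W)[4L] < 1L) stop("need at least one attention map", call. = FALSE)
  if (dim(W)[3L] != dim(F)[3L])
    stop("attention head channel count does not match feature maps", call. = FALSE)
  out <- convF(F, W, b, 1L, 0L)$y
  out <- out * (out > 0)
  array(out, dim(out)[1:3])
}

#' Part-feature maps from attention gating
#'
#' Multiplies each attention map element-wise with every feature channel,
#' producing one gated H x W x M stack per attention map.
#'
#' @param F An H x W x M feature array.
#' @param A An H x W x N attention array with the same spatial dimensions.
#' @return A list of N arrays, each H x W x M.
#' @export
partFeatureMaps <- function(F, A) {
  F <- if (is.matrix(F)) array(F, c(dim(F), 1L)) else F
  A <- if (is.matrix(A)) array(A, c(dim(A), 1L)) else A
  checkSpatialMatch(F, A)
  lapply(seq_len(dim(A)[3L]), function(i) {
    F * as.vector(A[, , i])
  })
}

#' Bilinear attention pooling
#'
#' Reduces each part-feature map by global average pooling: row i of the
#' returned matrix is the spatial mean of the i-th attention map multiplied
#' element-wise into every feature channel. The N x M result is the
#' part-feature matrix that feeds the linear classifier.
#'
#' @inheritParams partFeatureMaps
#' @return An N x M numeric matrix.
#' @export
bap <- function(F, A) {
  F <- if (is.matrix(F)) array(F, c(dim(F), 1L)) else F
  A <- if (is.matrix(A)) array(A, c(dim(A), 1L)) else A
  checkSpatialMatch(F, A)
  d <- dim(F)
  HW <- d[1L] * d[2L]
  crossprod(matrix(A, HW, dim(A)[3L]), matrix(F, HW, d[3L])) / HW
}

checkSpatialMatch <- function(F, A) {
  if (!all(dim(F)[1:2] == dim(A)[1:2]))
    stop("feature maps and attention maps differ in spatial dimensions",
         call. = FALSE)
  invisible(TRUE)
}

#' Classify a part-feature matrix
#'
#' Flattens the part-feature matrix (column-major, part index fastest),
#' L2-normalizes it, applies a linear map and a softmax.
#'
#' @param P An N x M part-feature matrix.
#' @param W A K x (N*M) weight matrix (K classes).
#' @param b Bias vector of length K.
#' @return Numeric vector of K class probabilities summing to 1.
#' @export
classifyFeatures <- function(P, W, b = NULL) {
  p <- as.vector(P)
  if (ncol(W) != length(p))
    stop(sprintf("classifier expects %d features, got %d", ncol(W), length(p)),
         call. = FALSE)
  r <- sqrt(sum(p * p))
  u <- if (r > 1e-12) p / r else p * 0
  z <- as.vector(W %*% u)
  if (!is.null(b)) z <- z + b
  e <- exp(z - max(z))
  e / sum(e)
}

#' Compute attention maps of an image under a trained model
#'
#' Runs the image through the backbone and attention head (evaluation
#' mode).
#'
#' @param model A [WSModel-class].
#' @param image An H x W matrix with intensities in [0, 1] (or quantized
#'   gray levels).
#' @return An H' x W' x N nonnegative attention array.
#' @export
attentionMaps <- function(model, image) {
  Fm <- extractFeatures(model, image)
  attentionHead(Fm, model@params$attnW, model@params$attnB)
}

#' Export attention maps as grayscale PNG files
#'
#' Writes each attention map, rescaled to [0, 1], to
#' `<dir>/<id>_attn_<i>.png` for visual inspection.
#'
#' @param A An H x W x N attention array.
#' @param dir Output directory (created if missing).
#' @param id Sample identifier used in file names.
#' @return Invisibly, the written file paths.
#' @export
exportAttentionMaps <- function(A, dir, id) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  paths <- character(dim(A)[3L])
  for (i in seq_len(dim(A)[3L])) {
    m <- normalizeAttention(A[, , i])
    paths[i] <- file.path(dir, sprintf("%s_attn_%d.png", id, i))
    png::writePNG(m, paths[i])
  }
  invisible(paths)
}
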