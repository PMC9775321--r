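# Attention-guided data augmentation: one attention map is selected per
# sample, min-max normalized, and thresholded into a crop mask (zoom into
# the attended region) and a drop mask (erase the attended region).

#' Min-max normalize an attention map
#'
#' Rescales a nonnegative map affinely to [0, 1]. A constant map (max equal
#' to min) maps to all zeros, so downstream thresholding treats it as
#' "nothing attended".
#'
#' @param Ai An H x W numeric matrix.
#' @return An H x W matrix with minimum 0 and maximum 1 (or all zeros).
#' @export
normalizeAttention <- function(Ai) {
  if (!all(is.finite(Ai))) stop("attention map contains non-finite values",
                                call. = FALSE)
  lo <- min(Ai)
  hi <- max(Ai)
  if (hi - lo <= 0) return(array(0, dim(Ai)))
  (Ai - lo) / (hi - lo)
}

#' Crop mask and minimal bounding box from a normalized attention map
#'
#' The mask marks positions whose normalized attention strictly exceeds
#' `theta`; the box is the smallest half-open rectangle (0-based
#' `rowStart/rowStop/colStart/colStop`) covering all marked positions.
#' If nothing exceeds the threshold the full-image box is returned with a
#' warning so training never stalls on a flat map.
#'
#' @param Ai A normalized H x W attention map (entries in [0, 1]).
#' @param theta Crop threshold in [0, 1] (default 0.5).
#' @param warn Emit a warning on the empty-mask fallback (default `TRUE`).
#' @return A list with `mask` (0/1 matrix), `box` (integer vector
#'   rowStart, rowStop, colStart, colStop; 0-based half-open), `theta`, and
#'   `fallback` (logical).
#' @export
cropMask <- function(Ai, theta = 0.5, warn = TRUE) {
  stopifnot(theta >= 0, theta <= 1)
  mask <- (Ai > theta) * 1L
  if (!any(mask == 1L)) {
    if (warn) warning("no attention value exceeds the crop threshold; ",
                      "falling back to the full-image box")
    return(list(mask = mask,
                box = c(0L, nrow(Ai), 0L, ncol(Ai)),
                theta = theta, fallback = TRUE))
  }
  rows <- which(rowSums(mask) > 0)
  cols <- which(colSums(mask) > 0)
  list(mask = mask,
       box = c(min(rows) - 1L, max(rows), min(cols) - 1L, max(cols)),
       theta = theta, fallback = FALSE)
}

#' Drop mask from a normalized attention map
#'
#' The complement indicator: positions whose normalized attention strictly
#' exceeds `theta` are set to 0 (erased), all others to 1. At equal
#' thresholds the crop and drop masks are exact complements.
#'
#' @inheritParams cropMask
#' @return A list with `mask` (0/1 matrix) and `theta`.
#' @export
dropMask <- function(Ai, theta = 0.5) {
  stopifnot(theta >= 0, theta <= 1)
  list(mask = 1L - (Ai > theta) * 1L, theta = theta)
}

# Separable bilinear resize of a matrix to outSize = c(H, W). Output pixel
# centers map proportionally onto input pixel centers (half-pixel offsets),
# so resizing to the input size is the identity.
bilinearResize <- function(m, outSize) {
  interpMat <- function(nIn, nOut) {
    src <- (seq_len(nOut) - 0.5) * nIn / nOut + 0.5
    src <- pmin(pmax(src, 1), nIn)
    r0 <- pmin(floor(src), nIn)
    r1 <- pmin(r0 + 1, nIn)
    w <- src - r0
    R <- matrix(0, nOut, nIn)
    R[cbind(seq_len(nOut), r0)] <- R[cbind(seq_len(nOut), r0)] + (1 - w)
    R[cbind(seq_len(nOut), r1)] <- R[cbind(seq_len(nOut), r1)] + w
    R
  }
  Rm <- interpMat(nrow(m), outSize[1L])
  Cm <- interpMat(ncol(m), outSize[2L])
  Rm %*% m %*% t(Cm)
}

#' Crop an image under an attention-grid bounding box and resize
#'
#' The box, expressed in (possibly coarser) attention-grid coordinates, is
#' mapped proportionally onto image pixels with half-open semantics, the
#' region is cut out, and the result is bilinearly resized to `outSize`.
#' A box degenerating to fewer than 2 pixels per side after mapping is
#' expanded before resizing.
#'
#' @param image An H x W numeric matrix.
#' @param box Integer vector rowStart, rowStop, colStart, colStop (0-based,
#'   half-open) on the attention grid.
#' @param outSize Output c(height, width).
#' @param gridSize c(height, width) of the grid the box lives on; defaults
#'   to the image dimensions (box already in pixel coordinates).
#' @return The cropped-and-resized numeric matrix.
#' @export
applyCrop <- function(image, box, outSize, gridSize = dim(image)) {
  image <- imageToUnit(image)
  H <- nrow(image); W <- ncol(image)
  sr <- H / gridSize[1L]
  sc <- W / gridSize[2L]
  r0 <- max(0L, floor(box[1L] * sr))
  r1 <- min(H, ceiling(box[2L] * sr))
  c0 <- max(0L, floor(box[3L] * sc))
  c1 <- min(W, ceiling(box[4L] * sc))
  # expand degenerate boxes to at least 2x2 before resizing
  while (r1 - r0 < 2L) { if (r0 > 0L) r0 <- r0 - 1L else r1 <- min(H, r1 + 1L) }
  while (c1 - c0 < 2L) { if (c0 > 0L) c0 <- c0 - 1L else c1 <- min(W, c1 + 1L) }
  crop <- image[(r0 + 1L):r1, (c0 + 1L):c1, drop = FALSE]
  if (all(dim(crop) == outSize)) return(crop)
  bilinearResize(crop, outSize)
}

#' Erase the attended region of an image
#'
#' Upsamples a drop mask to image resolution by nearest-neighbor
#' replication and multiplies it into the image.
#'
#' @param image An H x W numeric matrix.
#' @param mask A 0/1 matrix on the attention grid.
#' @return The masked image.
#' @export
applyDrop <- function(image, mask) {
  image <- imageToUnit(image)
  H <- nrow(image); W <- ncol(image)
  ri <- pmin(nrow(mask), floor((seq_len(H) - 1L) * nrow(mask) / H) + 1L)
  ci <- pmin(ncol(mask), floor((seq_len(W) - 1L) * ncol(mask) / W) + 1L)
  image * mask[ri, ci, drop = FALSE]
}

#' Attention-guided crop and drop augmentation of a batch
#'
#' For every image one attention map index is drawn uniformly with the
#' seeded generator; that map is normalized and drives both the crop and
#' the drop variant (a single shared draw; set `sharedMap = FALSE` for
#' independent draws).
#'
#' @param images List of H x W image matrices.
#' @param A List of H' x W' x N attention arrays, one per image.
#' @param thetaC,thetaD Crop and drop thresholds in [0, 1] (defaults 0.5).
#' @param seed Integer seed for the map selection.
#' @param outSize Output size of the cropped images (defaults to the input
#'   image size).
#' @param sharedMap Use one map draw for both crop and drop (default) or
#'   independent draws.
#' @param sampleThresholds If `TRUE`, draw `thetaC` and `thetaD` uniformly
#'   from [0.4, 0.6] for this batch instead of using the fixed values.
#' @return A list with `cropped` (list of matrices), `dropped` (list of
#'   matrices), `cropIdx` and `dropIdx` (1-based chosen map indices), and
#'   the thresholds used.
#' @export
augmentBatch <- function(images, A, thetaC = 0.5, thetaD = 0.5, seed = 1L,
                         outSize = NULL, sharedMap = TRUE,
                         sampleThresholds = FALSE) {
  stopifnot(length(images) == length(A))
  n <- length(images)
  N <- dim(A[[1L]])[3L]
  withSeed(seed, {
    if (sampleThresholds) {
      thetaC <- stats::runif(1L, 0.4, 0.6)
      thetaD <- stats::runif(1L, 0.4, 0.6)
    }
    cropIdx <- sample.int(N, n, replace = TRUE)
    dropIdx <- if (sharedMap) cropIdx else sample.int(N, n, replace = TRUE)
  })
  cropped <- vector("list", n)
  dropped <- vector("list", n)
  for (i in seq_len(n)) {
    img <- imageToUnit(images[[i]])
    if (is.null(outSize)) outSize <- dim(img)
    Anorm <- normalizeAttention(A[[i]][, , cropIdx[i]])
    cm <- cropMask(Anorm, thetaC, warn = FALSE)
    cropped[[i]] <- applyCrop(img, cm$box, outSize,
                              gridSize = dim(Anorm))
    Dnorm <- if (sharedMap) Anorm else normalizeAttention(A[[i]][, , dropIdx[i]])
    dm <- dropMask(Dnorm, thetaD)
    dropped[[i]] <- applyDrop(img, dm$mask)
  }
  list(cropped = cropped, dropped = dropped,
       cropIdx = cropIdx, dropIdx = dropIdx,
       thetaC = thetaC, thetaD = thetaD)
}
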