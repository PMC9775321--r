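# Deterministic synthetic slice and volume generator. Positive-class
# slices carry a localized disk of extra intensity (the planted "lesion")
# on a smooth elliptical background; negative-class slices carry background
# and noise only. The generator is the ground-truth source for every
# end-to-end test: lesion centers and textured slice indices are recorded.

#' Construct a synthetic dataset specification
#'
#' @param imageSize Height and width of each slice (default `c(32, 32)`).
#' @param nPerClass Slices per class (default 200).
#' @param lesionRadius Lesion disk radius in pixels (default 4).
#' @param lesionContrast Lesion intensity offset in [0, 1] (default 0.5).
#' @param noiseSd Additive Gaussian noise standard deviation (default
#'   0.05); noise is added before clipping to [0, 1] and quantization.
#' @param seed Integer seed; the same spec is bitwise reproducible.
#' @param grayLevels Quantization levels (default 256).
#' @return A [SyntheticSpec-class].
#' @export
syntheticSpec <- function(imageSize = c(32L, 32L), nPerClass = 200L,
                          lesionRadius = 4, lesionContrast = 0.5,
                          noiseSd = 0.05, seed = 1L, grayLevels = 256L) {
  methods::new("SyntheticSpec", imageSize = as.integer(imageSize),
               nPerClass = as.integer(nPerClass),
               lesionRadius = as.numeric(lesionRadius),
               lesionContrast = as.numeric(lesionContrast),
               noiseSd = as.numeric(noiseSd), seed = as.integer(seed),
               grayLevels = as.integer(grayLevels))
}

# Smooth elliptical background shared by both classes (deterministic, so at
# zero noise the between-class mean difference is supported exactly on the
# lesion disks).
ellipticalBackground <- function(H, W) {
  r <- matrix(seq_len(H), H, W)
  c <- matrix(seq_len(W), H, W, byrow = TRUE)
  d2 <- ((r - (H + 1) / 2) / (0.42 * H))^2 + ((c - (W + 1) / 2) / (0.46 * W))^2
  0.45 * pmax(0, 1 - d2)
}

lesionDisk <- function(H, W, center, radius) {
  r <- matrix(seq_len(H), H, W)
  c <- matrix(seq_len(W), H, W, byrow = TRUE)
  ((r - center[1L])^2 + (c - center[2L])^2 <= radius^2) * 1
}

#' Generate a labeled synthetic slice dataset
#'
#' Produces `2 * nPerClass` quantized grayscale slices. Positive slices add
#' a disk of intensity `lesionContrast` centered at a class-consistent
#' location jittered uniformly by up to 10% of the image size, so a
#' classifier must localize rather than memorize coordinates. With
#' `lesionContrast = 0` the two classes are generated by identical
#' distributions.
#'
#' @param spec A [SyntheticSpec-class].
#' @return A [SliceDataset-class]; lesion centers of positive slices are
#'   recorded in `lesionCenters()`.
#' @export
makeSliceDataset <- function(spec) {
  methods::validObject(spec)
  H <- spec@imageSize[1L]; W <- spec@imageSize[2L]
  G <- spec@grayLevels
  bg <- ellipticalBackground(H, W)
  base <- c(0.60 * H, 0.42 * W)   # class-consistent lesion anchor
  n <- spec@nPerClass
  images <- vector("list", 2L * n)
  centers <- matrix(NA_real_, 2L * n, 2L)
  withSeed(subSeed(spec@seed, "data"), {
    for (i in seq_len(2L * n)) {
      pos <- i > n
      img <- bg
      if (pos) {
        ctr <- base + stats::runif(2L, -0.1, 0.1) * c(H, W)
        img <- img + spec@lesionContrast * lesionDisk(H, W, ctr, spec@lesionRadius)
        centers[i, ] <- ctr
      }
      if (spec@noiseSd > 0)
        img <- img + matrix(stats::rnorm(H * W, sd = spec@noiseSd), H, W)
      q <- matrix(as.integer(round(pmin(pmax(img, 0), 1) * (G - 1L))), H, W)
      attr(q, "grayLevels") <- G
      images[[i]] <- q
    }
  })
  labels <- factor(rep(c("negative", "positive"), each = n),
                   levels = c("negative", "positive"))
  methods::new("SliceDataset", images = images, labels = labels,
               sourceIds = sprintf("%s_%04d", labels, c(seq_len(n), seq_len(n))),
               lesionCenters = centers, grayLevels = G)
}

#' Generate a synthetic 3D volume with known informative slices
#'
#' A fraction of the axial slices carry textured content (background plus
#' strong noise, hence high gray-level entropy); the remaining slices are
#' constant (zero entropy). The textured slice indices are returned as
#' ground truth for entropy-based slice selection.
#'
#' @param spec A [SyntheticSpec-class] (supplies image size, seed, gray
#'   levels).
#' @param nSlices Number of axial slices (default 61).
#' @param informativeFraction Fraction of textured slices in (0, 1]
#'   (default `32 / 61`).
#' @return A list with `volume` (H x W x nSlices numeric array, values in
#'   [0, 1]) and `textured` (0-based indices of the textured slices).
#' @export
makeVolume <- function(spec, nSlices = 61L, informativeFraction = 32 / 61) {
  methods::validObject(spec)
  stopifnot(nSlices >= 1L, informativeFraction > 0, informativeFraction <= 1)
  H <- spec@imageSize[1L]; W <- spec@imageSize[2L]
  nTex <- max(1L, round(informativeFraction * nSlices))
  bg <- ellipticalBackground(H, W)
  sd <- max(spec@noiseSd, 0.1)
  withSeed(subSeed(spec@seed, "volume"), {
    tex <- sort(sample.int(nSlices, nTex))
    vol <- array(0.5, c(H, W, nSlices))   # constant, zero-entropy filler
    for (i in tex) {
      img <- bg + matrix(stats::rnorm(H * W, sd = sd), H, W)
      vol[, , i] <- pmin(pmax(img, 0), 1)
    }
    list(volume = vol, textured = tex - 1L)
  })
}

#' Write a volume as NIfTI
#'
#' @param volume An H x W x S numeric array.
#' @param path Output `.nii` or `.nii.gz` path.
#' @export
writeVolume <- function(volume, path) {
  RNifti::writeNifti(RNifti::asNifti(volume), path)
  invisible(path)
}

#' Write a slice dataset as a ready-to-train directory tree
#'
#' Creates one subdirectory per class containing PNG slices, plus a JSON
#' ground-truth manifest (`manifest.json`) with labels and planted lesion
#' centers.
#'
#' @param dataset A [SliceDataset-class].
#' @param dir Output directory.
#' @return Invisibly, the manifest path.
#' @export
writeSliceDataset <- function(dataset, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  G <- dataset@grayLevels
  entries <- vector("list", length(dataset@images))
  for (i in seq_along(dataset@images)) {
    cl <- as.character(dataset@labels[i])
    cdir <- file.path(dir, cl)
    dir.create(cdir, showWarnings = FALSE)
    fn <- sprintf("%s.png", dataset@sourceIds[i])
    png::writePNG(dataset@images[[i]] / (G - 1L), file.path(cdir, fn))
    ctr <- dataset@lesionCenters[i, ]
    entries[[i]] <- list(id = dataset@sourceIds[i], class = cl,
                         file = file.path(cl, fn),
                         lesion_center = if (all(is.finite(ctr))) ctr else NULL)
  }
  mpath <- file.path(dir, "manifest.json")
  jsonlite::write_json(list(gray_levels = G, samples = entries), mpath,
                       auto_unbox = TRUE, digits = NA, null = "null")
  invisible(mpath)
}

#' Read a slice dataset written by [writeSliceDataset()]
#'
#' @param dir Directory containing class subfolders and `manifest.json`.
#' @return A [SliceDataset-class].
#' @export
readSliceDataset <- function(dir) {
  mpath <- file.path(dir, "manifest.json")
  if (!file.exists(mpath)) stop(sprintf("no manifest.json under '%s'", dir),
                                call. = FALSE)
  man <- jsonlite::read_json(mpath)
  G <- as.integer(man$gray_levels)
  n <- length(man$samples)
  images <- vector("list", n)
  labels <- character(n)
  ids <- character(n)
  centers <- matrix(NA_real_, n, 2L)
  for (i in seq_len(n)) {
    s <- man$samples[[i]]
    m <- png::readPNG(file.path(dir, s$file))
    if (length(dim(m)) == 3L) m <- m[, , 1L]
    q <- matrix(as.integer(round(m * (G - 1L))), nrow(m), ncol(m))
    attr(q, "grayLevels") <- G
    images[[i]] <- q
    labels[i] <- s$class
    ids[i] <- s$id
    if (!is.null(s$lesion_center))
      centers[i, ] <- unlist(s$lesion_center)
  }
  methods::new("SliceDataset", images = images,
               labels = factor(labels, levels = c("negative", "positive")),
               sourceIds = ids, lesionCenters = centers, grayLevels = G)
}
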