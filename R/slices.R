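# Slice handling: gray-level image entropy, entropy-based slice ranking,
# volume loading (NIfTI or PNG directories) with per-volume min-max
# quantization, and the stratified dataset partition.

#' Shannon entropy of a gray-level histogram
#'
#' Computes H = -sum_g p_g log2 p_g over the empirical gray-level
#' distribution of a quantized slice; bins with zero probability contribute
#' nothing. Entropy is measured in bits, so it is bounded by
#' log2(grayLevels).
#'
#' @param slice An integer matrix with values in `[0, grayLevels - 1]`.
#' @param grayLevels Number of gray levels G (default 256).
#' @return Nonnegative entropy in bits.
#' @export
computeEntropy <- function(slice, grayLevels = 256L) {
  if (length(slice) == 0L) stop("empty image", call. = FALSE)
  if (grayLevels < 2L) stop("grayLevels must be >= 2", call. = FALSE)
  v <- as.integer(slice)
  if (any(v < 0L) || any(v >= grayLevels))
    stop("pixel values outside [0, grayLevels - 1]", call. = FALSE)
  p <- tabulate(v + 1L, nbins = grayLevels) / length(v)
  p <- p[p > 0]
  -sum(p * log2(p))
}

#' Rank slices of a volume by image entropy
#'
#' Returns the `k` most informative slices, sorted by descending entropy;
#' ties are broken by ascending slice index (stable). The default `k = 32`
#' matches the number of axial slices retained per 3D scan.
#'
#' @param volume A list of quantized slice matrices, or a 3D array whose
#'   third axis indexes slices.
#' @param k Number of slices to keep (default 32).
#' @param grayLevels Number of gray levels (default 256).
#' @return A data frame with columns `slice_index` (0-based) and `entropy`
#'   (bits), `k` rows, entropy-descending.
#' @export
rankSlices <- function(volume, k = 32L, grayLevels = 256L) {
  slices <- volumeSlices(volume)
  if (k > length(slices))
    stop(sprintf("k = %d exceeds the %d available slices", k, length(slices)),
         call. = FALSE)
  ent <- vapply(slices, computeEntropy, numeric(1L), grayLevels = grayLevels)
  ord <- order(-ent, seq_along(ent))[seq_len(k)]
  data.frame(slice_index = ord - 1L, entropy = ent[ord])
}

volumeSlices <- function(volume) {
  if (is.list(volume)) return(volume)
  if (length(dim(volume)) != 3L)
    stop("volume must be a list of matrices or a 3D array", call. = FALSE)
  lapply(seq_len(dim(volume)[3L]), function(i) volume[, , i])
}

#' Load a volume as an ordered list of quantized gray slices
#'
#' Reads either a NIfTI file (slices taken along `axis`, default the third
#' array axis, treated as axial) or a directory of PNG slices in
#' lexicographic filename order. Intensities are min-max quantized to
#' `grayLevels` levels per volume; a constant volume quantizes to all
#' zeros.
#'
#' @param path Path to a `.nii`/`.nii.gz` file or a directory of PNGs.
#' @param grayLevels Number of gray levels (default 256).
#' @param axis Array axis treated as the slice axis for NIfTI input
#'   (default 3).
#' @return A list of integer slice matrices; each carries attributes
#'   `sourceId` and `grayLevels`.
#' @export
loadVolume <- function(path, grayLevels = 256L, axis = 3L) {
  if (dir.exists(path)) {
    files <- sort(list.files(path, pattern = "\\.png$", full.names = TRUE))
    if (length(files) == 0L)
      stop(sprintf("no PNG slices found in '%s'", path), call. = FALSE)
    raw <- lapply(files, function(f) {
      m <- png::readPNG(f)
      if (length(dim(m)) == 3L) m <- m[, , 1L]   # first channel of RGB(A)
      m
    })
    arr <- array(unlist(raw), c(dim(raw[[1L]]), length(raw)))
  } else {
    if (!file.exists(path)) stop(sprintf("cannot read '%s'", path), call. = FALSE)
    img <- tryCatch(suppressWarnings(RNifti::readNifti(path)),
                    error = function(e)
                      stop(sprintf("not a readable NIfTI file: %s",
                                   conditionMessage(e)), call. = FALSE))
    arr <- as.array(img)
    nd <- length(dim(arr))
    if (nd == 2L) dim(arr) <- c(dim(arr), 1L)
    if (length(dim(arr)) != 3L)
      stop(sprintf("expected a 3D volume but got %d dimensions (dim %s)",
                   nd, paste(dim(arr), collapse = "x")), call. = FALSE)
    if (axis != 3L) arr <- aperm(arr, c(setdiff(1:3, axis), axis))
  }
  q <- quantizeVolume(arr, grayLevels)
  id <- basename(path)
  lapply(seq_len(dim(q)[3L]), function(i) {
    s <- q[, , i]
    attr(s, "sourceId") <- sprintf("%s#%d", id, i - 1L)
    attr(s, "grayLevels") <- grayLevels
    s
  })
}

quantizeVolume <- function(arr, grayLevels) {
  lo <- min(arr)
  hi <- max(arr)
  if (hi - lo <= 0) {
    out <- array(0L, dim(arr))
  } else {
    out <- array(as.integer(round((arr - lo) / (hi - lo) * (grayLevels - 1L))),
                 dim(arr))
  }
  out
}

#' Select and export the most informative slices of a volume
#'
#' Ranks slices by entropy, writes the selected ones as PNGs and a TSV
#' manifest (`source_id`, `slice_index`, `entropy_bits`).
#'
#' @param path Volume path, as in [loadVolume()].
#' @param outDir Output directory.
#' @param k Number of slices to keep (default 32).
#' @param grayLevels Number of gray levels.
#' @return Invisibly, the manifest data frame.
#' @export
exportSlices <- function(path, outDir, k = 32L, grayLevels = 256L) {
  vol <- loadVolume(path, grayLevels)
  rk <- rankSlices(vol, k, grayLevels)
  dir.create(outDir, recursive = TRUE, showWarnings = FALSE)
  ids <- character(nrow(rk))
  for (i in seq_len(nrow(rk))) {
    sl <- vol[[rk$slice_index[i] + 1L]]
    ids[i] <- attr(sl, "sourceId")
    png::writePNG(sl / (grayLevels - 1L),
                  file.path(outDir, sprintf("slice_%03d.png", rk$slice_index[i])))
  }
  manifest <- data.frame(source_id = ids, slice_index = rk$slice_index,
                         entropy_bits = rk$entropy)
  utils::write.table(manifest, file.path(outDir, "slices.tsv"),
                     sep = "\t", row.names = FALSE, quote = FALSE)
  invisible(manifest)
}

#' Stratified train/validation/test split
#'
#' Partitions each class independently: `floor(n * r_train)` ids to train,
#' `floor(n * r_val)` to validation, and the remainder to test, after a
#' seeded shuffle. With 2560 ids per class at ratio 8:1:1 this yields
#' 2048/256/256. Repeated calls with the same seed are identical.
#'
#' @param idsByClass Named list mapping class label to a character/integer
#'   vector of sample ids.
#' @param ratio Nonnegative train/val/test weights (default `c(8, 1, 1)`).
#' @param seed Integer seed for the shuffle.
#' @return A [DatasetSplit-class].
#' @export
splitDataset <- function(idsByClass, ratio = c(8, 1, 1), seed = 1L) {
  if (length(ratio) != 3L || any(ratio < 0) || sum(ratio) <= 0)
    stop("ratio must be three nonnegative values with a positive sum",
         call. = FALSE)
  if (is.null(names(idsByClass)) || any(!nzchar(names(idsByClass))))
    stop("idsByClass must be a named list", call. = FALSE)
  if (any(vapply(idsByClass, length, 1L) < 3L))
    stop("each class needs at least 3 samples", call. = FALSE)
  r <- ratio / sum(ratio)
  rows <- withSeed(subSeed(seed, "split"), {
    lapply(names(idsByClass), function(cl) {
      ids <- as.character(idsByClass[[cl]])
      ids <- ids[sample.int(length(ids))]
      n <- length(ids)
      nTrain <- floor(n * r[1L])
      nVal <- floor(n * r[2L])
      part <- c(rep("train", nTrain), rep("val", nVal),
                rep("test", n - nTrain - nVal))
      data.frame(id = ids, class = cl, partition = part)
    })
  })
  methods::new("DatasetSplit", assignments = do.call(rbind, rows))
}

#' Write a dataset split as TSV
#'
#' @param split A [DatasetSplit-class].
#' @param path Output TSV path (columns id, class, partition).
#' @export
writeSplit <- function(split, path) {
  utils::write.table(split@assignments, path, sep = "\t",
                     row.names = FALSE, quote = FALSE)
  invisible(path)
}
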