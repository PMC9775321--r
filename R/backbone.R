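# Attention-gated bottleneck residual blocks and the full backbone.
#
# A block computes, for input X:
#   F   = BN(conv1x1(relu(BN(conv3x3(relu(BN(conv1x1(X))))))))   (bottleneck)
#   F'  = Mc(F) (*) F          channel gate, broadcast over positions
#   F'' = Ms(F') (*) F'        spatial gate, broadcast over channels
#   Xb  = X + F''              residual fusion (projection shortcut when
#                              shapes differ); no activation after the sum,
#                              so F'' = 0 implies Xb = X exactly.

initConv <- function(kh, kw, cin, cout) {
  array(stats::rnorm(kh * kw * cin * cout, sd = sqrt(2 / (kh * kw * cin))),
        c(kh, kw, cin, cout))
}

initBlockParams <- function(cin, cmid, cout, stride, reduction, sgKernel = 7L) {
  project <- (cin != cout) || (stride != 1L)
  h <- max(1L, cout %/% reduction)
  p <- list(
    W1 = initConv(1L, 1L, cin, cmid),
    g1 = rep(1, cmid), b1 = rep(0, cmid),
    W2 = initConv(3L, 3L, cmid, cmid),
    g2 = rep(1, cmid), b2 = rep(0, cmid),
    W3 = initConv(1L, 1L, cmid, cout),
    g3 = rep(1, cout), b3 = rep(0, cout),
    cgW0 = matrix(stats::rnorm(h * cout, sd = sqrt(2 / cout)), h, cout),
    cgW1 = matrix(stats::rnorm(cout * h, sd = sqrt(2 / h)), cout, h),
    sgW = array(stats::rnorm(sgKernel * sgKernel * 2,
                             sd = sqrt(2 / (sgKernel * sgKernel * 2))),
                c(sgKernel, sgKernel, 2L, 1L)),
    sgb = 0
  )
  if (project) {
    p$pW <- initConv(1L, 1L, cin, cout)
    p$pg <- rep(1, cout)
    p$pb <- rep(0, cout)
  }
  p
}

initBlockState <- function(cmid, cout, project) {
  s <- list(rm1 = rep(0, cmid), rv1 = rep(1, cmid),
            rm2 = rep(0, cmid), rv2 = rep(1, cmid),
            rm3 = rep(0, cout), rv3 = rep(1, cout))
  if (project) {
    s$prm <- rep(0, cout)
    s$prv <- rep(1, cout)
  }
  s
}

blockF <- function(x, p, st, stride, train, bypass, momentum = 0.1) {
  c1 <- convF(x, p$W1, NULL, 1L, 0L)
  n1 <- bnF(c1$y, p$g1, p$b1, st$rm1, st$rv1, train, momentum)
  r1 <- reluF(n1$y)
  c2 <- convF(r1$y, p$W2, NULL, stride, 1L)
  n2 <- bnF(c2$y, p$g2, p$b2, st$rm2, st$rv2, train, momentum)
  r2 <- reluF(n2$y)
  c3 <- convF(r2$y, p$W3, NULL, 1L, 0L)
  n3 <- bnF(c3$y, p$g3, p$b3, st$rm3, st$rv3, train, momentum)
  if (bypass) {
    cg <- NULL; sg <- NULL
    Fpp <- n3$y
  } else {
    cg <- cgF(n3$y, p$cgW0, p$cgW1)
    sg <- sgF(cg$y, p$sgW, p$sgb)
    Fpp <- sg$y
  }
  st$rm1 <- n1$rm; st$rv1 <- n1$rv
  st$rm2 <- n2$rm; st$rv2 <- n2$rv
  st$rm3 <- n3$rm; st$rv3 <- n3$rv
  if (!is.null(p$pW)) {
    pc <- convF(x, p$pW, NULL, stride, 0L)
    pn <- bnF(pc$y, p$pg, p$pb, st$prm, st$prv, train, momentum)
    st$prm <- pn$rm; st$prv <- pn$rv
    sc <- pn$y
    pcache <- list(conv = pc$cache, bn = pn$cache)
  } else {
    sc <- x
    pcache <- NULL
  }
  list(y = sc + Fpp, state = st,
       cache = list(c1 = c1$cache, n1 = n1$cache, m1 = r1$mask,
                    c2 = c2$cache, n2 = n2$cache, m2 = r2$mask,
                    c3 = c3$cache, n3 = n3$cache,
                    cg = if (!bypass) cg$cache, sg = if (!bypass) sg$cache,
                    proj = pcache, bypass = bypass))
}

blockB <- function(dy, p, cache) {
  g <- list()
  # gated residual branch
  if (cache$bypass) {
    dn3 <- dy
    g$cgW0 <- array(0, dim(p$cgW0)); g$cgW1 <- array(0, dim(p$cgW1))
    g$sgW <- array(0, dim(p$sgW)); g$sgb <- 0
  } else {
    bs <- sgB(dy, p$sgW, cache$sg)
    g$sgW <- bs$dW; g$sgb <- bs$db
    bc <- cgB(bs$dx, p$cgW0, p$cgW1, cache$cg)
    g$cgW0 <- bc$dW0; g$cgW1 <- bc$dW1
    dn3 <- bc$dx
  }
  b3 <- bnB(dn3, cache$n3)
  g$g3 <- b3$dg; g$b3 <- b3$db
  v3 <- convB(b3$dx, p$W3, cache$c3)
  g$W3 <- v3$dW
  dr2 <- reluB(v3$dx, cache$m2)
  b2 <- bnB(dr2, cache$n2)
  g$g2 <- b2$dg; g$b2 <- b2$db
  v2 <- convB(b2$dx, p$W2, cache$c2)
  g$W2 <- v2$dW
  dr1 <- reluB(v2$dx, cache$m1)
  b1 <- bnB(dr1, cache$n1)
  g$g1 <- b1$dg; g$b1 <- b1$db
  v1 <- convB(b1$dx, p$W1, cache$c1)
  g$W1 <- v1$dW
  dx <- v1$dx
  # shortcut branch
  if (!is.null(cache$proj)) {
    pb <- bnB(dy, cache$proj$bn)
    g$pg <- pb$dg; g$pb <- pb$db
    pv <- convB(pb$dx, p$pW, cache$proj$conv)
    g$pW <- pv$dW
    dx <- dx + pv$dx
  } else {
    dx <- dx + dy
  }
  list(dx = dx, grads = g[names(p)])
}

# ---- architecture definitions ----------------------------------------

archBlocks <- function(arch) {
  switch(arch,
    tiny = list(
      list(cin = 8L, cmid = 4L, cout = 16L, stride = 2L),
      list(cin = 16L, cmid = 8L, cout = 32L, stride = 2L)),
    resnet50 = {
      stage <- function(cin, cmid, cout, n, firstStride) {
        out <- list(list(cin = cin, cmid = cmid, cout = cout, stride = firstStride))
        for (i in seq_len(n - 1L))
          out[[i + 1L]] <- list(cin = cout, cmid = cmid, cout = cout, stride = 1L)
        out
      }
      c(stage(64L, 64L, 256L, 3L, 1L),
        stage(256L, 128L, 512L, 4L, 2L),
        stage(512L, 256L, 1024L, 6L, 2L),
        stage(1024L, 512L, 2048L, 3L, 2L))
    },
    stop(sprintf("unknown architecture '%s'", arch), call. = FALSE))
}

#' Build the attention-gated residual backbone
#'
#' Assembles the full model: a residual feature extractor whose bottleneck
#' blocks each carry a channel+spatial attention gate, a 1x1-convolution
#' attention head producing `nMaps` nonnegative attention maps, and a linear
#' classifier over the bilinear-attention-pooled part-feature matrix.
#'
#' Two architectures are provided: `"resnet50"` with the standard
#' 3+4+6+3 stage layout (every bottleneck replaced by its attention-gated
#' version), and `"tiny"`, a two-stage variant with identical block
#' semantics and under 100k parameters, intended for CPU-scale experiments.
#'
#' @param arch `"tiny"` or `"resnet50"`.
#' @param inputSize Integer height and width of input images.
#' @param inChannels Input channels (grayscale images may be replicated to
#'   3 channels by setting this to 3; default 1 for `tiny`, 3 for
#'   `resnet50`).
#' @param nMaps Number of attention maps N (default 32).
#' @param reduction Channel-gate reduction ratio (default 16; clipped so the
#'   hidden layer keeps at least one unit).
#' @param classes Character vector of the two class names; the second entry
#'   is the positive (disease) class.
#' @param seed Integer seed for parameter initialization.
#' @param pretrained If `TRUE`, request externally trained initial weights
#'   for the non-gate parameters. No weight source is bundled with the
#'   package, so this raises an explicit error rather than silently falling
#'   back to random initialization.
#' @return A [WSModel-class] object.
#' @export
buildBackbone <- function(arch = c("tiny", "resnet50"),
                          inputSize = c(32L, 32L),
                          inChannels = NULL,
                          nMaps = 32L,
                          reduction = 16L,
                          classes = c("negative", "positive"),
                          seed = 1L,
                          pretrained = FALSE) {
  arch <- match.arg(arch)
  if (pretrained)
    stop("pretrained weights are not bundled and cannot be fetched here; ",
         "load a checkpoint with readModel() instead", call. = FALSE)
  if (nMaps < 1L) stop("nMaps must be >= 1", call. = FALSE)
  if (is.null(inChannels)) inChannels <- if (arch == "tiny") 1L else 3L
  blocks <- archBlocks(arch)
  stem <- if (arch == "tiny")
    list(k = 3L, stride = 2L, pad = 1L, cout = 8L, maxpool = FALSE)
  else
    list(k = 7L, stride = 2L, pad = 3L, cout = 64L, maxpool = TRUE)
  M <- blocks[[length(blocks)]]$cout
  config <- list(arch = arch, inputSize = as.integer(inputSize),
                 inChannels = as.integer(inChannels), stem = stem,
                 blocks = blocks, nMaps = as.integer(nMaps),
                 reduction = as.integer(reduction), featureChannels = M,
                 classes = classes, bypassGates = FALSE, seed = as.integer(seed))
  withSeed(seed, {
    params <- list(
      stemW = initConv(stem$k, stem$k, inChannels, stem$cout),
      stemG = rep(1, stem$cout), stemB = rep(0, stem$cout),
      blocks = lapply(blocks, function(bk)
        initBlockParams(bk$cin, bk$cmid, bk$cout, bk$stride, reduction)),
      attnW = initConv(1L, 1L, M, nMaps),
      attnB = rep(0, nMaps),
      headW = matrix(0, length(classes), nMaps * M),
      headB = rep(0, length(classes))
    )
    state <- list(
      stemRm = rep(0, stem$cout), stemRv = rep(1, stem$cout),
      blocks = lapply(blocks, function(bk)
        initBlockState(bk$cmid, bk$cout,
                       (bk$cin != bk$cout) || (bk$stride != 1L)))
    )
    methods::new("WSModel", config = config, params = params, state = state,
                 centers = matrix(0, nMaps, M))
  })
}

#' Create a standalone attention-gated bottleneck block
#'
#' @param cin,cmid,cout Input, bottleneck and output channel counts.
#' @param stride Stride of the 3x3 convolution (a projection shortcut is
#'   added automatically when shapes differ).
#' @param reduction Channel-gate reduction ratio.
#' @param seed Integer seed for initialization.
#' @return A list with `params`, `state`, and `stride`, consumable by
#'   [improvedBlockForward()].
#' @export
improvedBlock <- function(cin, cmid, cout, stride = 1L, reduction = 16L,
                          seed = 1L) {
  project <- (cin != cout) || (stride != 1L)
  withSeed(seed, list(
    params = initBlockParams(cin, cmid, cout, stride, reduction),
    state = initBlockState(cmid, cout, project),
    stride = as.integer(stride)))
}

#' Forward pass of an attention-gated bottleneck block
#'
#' Computes the bottleneck residual, gates it with the channel and then the
#' spatial attention module, and adds the (possibly projected) shortcut:
#' the output equals the input exactly when the gated residual is zero.
#' Batch-norm layers use their running moments (evaluation mode), so the
#' mapping is deterministic.
#'
#' @param X An H x W x C input array (single sample).
#' @param block A block from [improvedBlock()].
#' @param bypass If `TRUE` both gates are clamped to 1, reducing the block
#'   to a plain bottleneck residual block.
#' @return The H' x W' x cout output array.
#' @export
improvedBlockForward <- function(X, block, bypass = FALSE) {
  x4 <- as4d(X)
  if (dim(x4)[3L] != dim(block$params$W1)[3L])
    stop(sprintf("input has %d channels but block expects %d",
                 dim(x4)[3L], dim(block$params$W1)[3L]), call. = FALSE)
  out <- blockF(x4, block$params, block$state, block$stride,
                train = FALSE, bypass = bypass)
  array(out$y, dim(out$y)[1:3])
}

# ---- full-model forward / backward ------------------------------------

# Forward through stem + blocks only; returns feature maps and caches.
backboneF <- function(params, state, config, x, train, bypass) {
  sc <- convF(x, params$stemW, NULL, config$stem$stride, config$stem$pad)
  sn <- bnF(sc$y, params$stemG, params$stemB, state$stemRm, state$stemRv, train)
  sr <- reluF(sn$y)
  state$stemRm <- sn$rm; state$stemRv <- sn$rv
  cur <- sr$y
  mp <- NULL
  if (isTRUE(config$stem$maxpool)) {
    mp <- maxPoolF(cur, 3L, 2L, 1L)
    cur <- mp$y
  }
  bcaches <- vector("list", length(config$blocks))
  for (i in seq_along(config$blocks)) {
    bo <- blockF(cur, params$blocks[[i]], state$blocks[[i]],
                 config$blocks[[i]]$stride, train, bypass)
    bcaches[[i]] <- bo$cache
    state$blocks[[i]] <- bo$state
    cur <- bo$y
  }
  list(F = cur, state = state,
       cache = list(stemConv = sc$cache, stemBn = sn$cache, stemMask = sr$mask,
                    mp = if (!is.null(mp)) mp$cache, blocks = bcaches))
}

backboneB <- function(dF, params, config, cache) {
  g <- list()
  cur <- dF
  gblocks <- vector("list", length(config$blocks))
  for (i in rev(seq_along(config$blocks))) {
    bb <- blockB(cur, params$blocks[[i]], cache$blocks[[i]])
    gblocks[[i]] <- bb$grads
    cur <- bb$dx
  }
  if (!is.null(cache$mp)) cur <- maxPoolB(cur, cache$mp)
  dsr <- reluB(cur, cache$stemMask)
  sb <- bnB(dsr, cache$stemBn)
  sv <- convB(sb$dx, params$stemW, cache$stemConv)
  list(grads = list(stemW = sv$dW, stemG = sb$dg, stemB = sb$db,
                    blocks = gblocks),
       dx = sv$dx)
}

# Full pipeline forward: backbone -> attention head -> BAP -> classifier.
modelForward <- function(params, state, config, x, train = FALSE,
                         bypass = isTRUE(config$bypassGates)) {
  bb <- backboneF(params, state, config, x, train, bypass)
  Fm <- bb$F
  ac <- convF(Fm, params$attnW, params$attnB, 1L, 0L)
  ar <- reluF(ac$y)
  A <- ar$y
  d <- dim(Fm)
  HW <- d[1L] * d[2L]
  M <- d[3L]; B <- d[4L]
  N <- config$nMaps
  P <- array(0, c(N, M, B))
  for (b in seq_len(B))
    P[, , b] <- crossprod(matrix(A[, , , b], HW, N),
                          matrix(Fm[, , , b], HW, M)) / HW
  Pflat <- matrix(P, N * M, B)
  r <- sqrt(colSums(Pflat * Pflat))
  rs <- pmax(r, 1e-12)
  U <- sweep(Pflat, 2L, rs, "/")
  logits <- params$headW %*% U + params$headB
  lm <- apply(logits, 2L, max)
  el <- exp(sweep(logits, 2L, lm))
  probs <- sweep(el, 2L, colSums(el), "/")
  list(F = Fm, A = A, P = P, logits = logits, probs = probs, state = bb$state,
       cache = list(backbone = bb$cache, attnConv = ac$cache,
                    attnMask = ar$mask, U = U, rs = rs, r = r, d = d))
}

# Backward from d(logits), an optional extra gradient on the normalized
# features U (used by the attention regularization term) and an optional
# extra gradient on P. Returns grads aligned with params and the gradient
# with respect to the input batch.
modelBackward <- function(params, config, fwd, dlogits, dPextra = NULL,
                          dUextra = NULL) {
  ch <- fwd$cache
  d <- ch$d
  HW <- d[1L] * d[2L]; M <- d[3L]; B <- d[4L]
  N <- config$nMaps
  dheadW <- tcrossprod(dlogits, ch$U)
  dheadB <- rowSums(dlogits)
  dU <- crossprod(params$headW, dlogits)
  if (!is.null(dUextra)) dU <- dU + dUextra
  dPflat <- sweep(dU - sweep(ch$U, 2L, colSums(dU * ch$U), "*"), 2L, ch$rs, "/")
  dPflat[, ch$r < 1e-12] <- 0
  dP <- array(dPflat, c(N, M, B))
  if (!is.null(dPextra)) dP <- dP + dPextra
  dA <- array(0, dim(fwd$A))
  dF <- array(0, dim(fwd$F))
  for (b in seq_len(B)) {
    Fmat <- matrix(fwd$F[, , , b], HW, M)
    Amat <- matrix(fwd$A[, , , b], HW, N)
    dA[, , , b] <- array(Fmat %*% t(dP[, , b]), c(d[1L], d[2L], N)) / HW
    dF[, , , b] <- array(Amat %*% dP[, , b], c(d[1L], d[2L], M)) / HW
  }
  dAc <- reluB(dA, ch$attnMask)
  av <- convB(dAc, params$attnW, ch$attnConv)
  dF <- dF + av$dx
  bbk <- backboneB(dF, params, config, ch$backbone)
  grads <- bbk$grads
  grads$attnW <- av$dW
  grads$attnB <- av$db
  grads$headW <- dheadW
  grads$headB <- dheadB
  list(grads = grads[names(params)], dx = bbk$dx)
}

#' Extract backbone feature maps
#'
#' Runs images through the attention-gated residual feature extractor only
#' (evaluation mode) and returns the final feature stack.
#'
#' @param model A [WSModel-class].
#' @param image An H x W matrix (or H x W x C array) with intensities in
#'   [0, 1].
#' @return An H' x W' x M feature array.
#' @export
extractFeatures <- function(model, image) {
  x <- prepInput(model, image)
  out <- backboneF(model@params, model@state, model@config, x,
                   train = FALSE, bypass = isTRUE(model@config$bypassGates))
  array(out$F, dim(out$F)[1:3])
}

# Convert one image (matrix in [0,1] or integer gray levels) to the model's
# input tensor, replicating channels when the model expects more than one.
prepInput <- function(model, image) {
  if (is.list(image)) return(toBatch(model, image))
  m <- imageToUnit(image)
  cfg <- model@config
  if (!all(dim(m)[1:2] == cfg$inputSize))
    m <- bilinearResize(m, cfg$inputSize)
  x <- array(0, c(dim(m)[1L], dim(m)[2L], cfg$inChannels, 1L))
  for (cc in seq_len(cfg$inChannels)) x[, , cc, 1L] <- m
  x
}

toBatch <- function(model, images) {
  xs <- lapply(images, function(im) prepInput(model, im))
  d <- dim(xs[[1L]])
  out <- array(0, c(d[1L], d[2L], d[3L], length(xs)))
  for (i in seq_along(xs)) out[, , , i] <- xs[[i]]
  out
}

# Accept integer gray-level matrices (converted to [0,1] intensities using
# their grayLevels attribute) or numeric matrices (used as-is).
imageToUnit <- function(image) {
  m <- image
  if (is.integer(m)) {
    g <- attr(m, "grayLevels") %||% 256L
    m <- m / (g - 1)
  }
  storage.mode(m) <- "double"
  m
}
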