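# Channel and spatial attention gates (the CBAM pair), batched internals
# plus the exported single-sample operations.

# ---- batched internals ------------------------------------------------

# Channel gate: per-channel global average and max pooling, a shared
# two-layer MLP (no biases, ReLU hidden), element-wise sum, sigmoid.
cgF <- function(x, W0, W1) {
  d <- dim(x)
  HW <- d[1L] * d[2L]; C <- d[3L]; B <- d[4L]
  m2 <- matrix(x, HW, C * B)
  avg <- matrix(colMeans(m2), C, B)
  idx <- max.col(t(m2), ties.method = "first")
  mx <- matrix(m2[cbind(idx, seq_len(C * B))], C, B)
  ha <- W0 %*% avg
  hm <- W0 %*% mx
  haR <- ha * (ha > 0)
  hmR <- hm * (hm > 0)
  s <- sigmoid(W1 %*% haR + W1 %*% hmR)   # C x B
  y <- array(m2 * rep(as.vector(s), each = HW), d)
  list(y = y, weights = s,
       cache = list(m2 = m2, avg = avg, mx = mx, idx = idx,
                    ha = ha, hm = hm, haR = haR, hmR = hmR,
                    s = s, d = d, HW = HW))
}

cgB <- function(dy, W0, W1, cache) {
  d <- cache$d
  HW <- cache$HW; C <- d[3L]; B <- d[4L]
  s <- cache$s
  dym <- matrix(dy, HW, C * B)
  dxm <- dym * rep(as.vector(s), each = HW)
  ds <- matrix(colSums(dym * cache$m2), C, B)
  dpre <- ds * s * (1 - s)
  dW1 <- tcrossprod(dpre, cache$haR) + tcrossprod(dpre, cache$hmR)
  dha <- crossprod(W1, dpre) * (cache$ha > 0)
  dhm <- crossprod(W1, dpre) * (cache$hm > 0)
  dW0 <- tcrossprod(dha, cache$avg) + tcrossprod(dhm, cache$mx)
  davg <- crossprod(W0, dha)
  dmx <- crossprod(W0, dhm)
  dxm <- dxm + rep(as.vector(davg) / HW, each = HW)
  lin <- cbind(cache$idx, seq_len(C * B))
  dxm[lin] <- dxm[lin] + as.vector(dmx)
  list(dx = array(dxm, d), dW0 = dW0, dW1 = dW1)
}

# Spatial gate: channel-wise mean and max maps, concatenated, 7x7 conv to a
# single map (padding preserves H x W), sigmoid, broadcast multiply.
sgF <- function(x, W, b) {
  d <- dim(x)
  C <- d[3L]
  xm <- chanMat(x)                      # (H*W*B) x C
  cm <- rowMeans(xm)
  cidx <- max.col(xm, ties.method = "first")
  cmx <- xm[cbind(seq_len(nrow(xm)), cidx)]
  pad <- (dim(W)[1L] - 1L) %/% 2L
  st <- aperm(array(c(cm, cmx), c(d[1L], d[2L], d[4L], 2L)), c(1L, 2L, 4L, 3L))
  cv <- convF(st, W, b, stride = 1L, pad = pad)
  sv <- as.vector(sigmoid(aperm(cv$y, c(1L, 2L, 4L, 3L))))   # length H*W*B
  ym <- xm * sv
  S <- array(sv, c(d[1L], d[2L], d[4L]))
  list(y = chanArr(ym, d), S = S,
       cache = list(xm = xm, sv = sv, cidx = cidx, conv = cv$cache, d = d))
}

sgB <- function(dy, W, cache) {
  d <- cache$d
  C <- d[3L]
  dym <- chanMat(dy)
  dxm <- dym * cache$sv
  dsv <- rowSums(dym * cache$xm)
  dpre <- dsv * cache$sv * (1 - cache$sv)
  dpreA <- aperm(array(dpre, c(d[1L], d[2L], d[4L], 1L)), c(1L, 2L, 4L, 3L))
  cb <- convB(dpreA, W, cache$conv)
  dst <- aperm(cb$dx, c(1L, 2L, 4L, 3L))       # [H, W, B, 2]
  dcm <- as.vector(dst[, , , 1L])
  dcmx <- as.vector(dst[, , , 2L])
  dxm <- dxm + dcm / C
  lin <- cbind(seq_len(nrow(dxm)), cache$cidx)
  dxm[lin] <- dxm[lin] + dcmx
  list(dx = chanArr(dxm, d), dW = cb$dW, db = cb$db)
}

# ---- exported single-sample operations --------------------------------

#' Create a channel-attention gate
#'
#' Builds the shared two-layer perceptron (no bias terms, ReLU hidden
#' activation) used by the channel-attention gate. The hidden width is
#' `max(1, floor(channels / reduction))`, so very narrow feature stacks
#' still get at least one hidden unit.
#'
#' @param channels Number of feature channels the gate acts on.
#' @param reduction Channel reduction ratio of the bottleneck MLP.
#' @param seed Integer seed for weight initialization.
#' @return A list with matrices `W0` (hidden x channels) and `W1`
#'   (channels x hidden).
#' @export
channelGate <- function(channels, reduction = 16, seed = 1L) {
  h <- max(1L, channels %/% reduction)
  withSeed(seed, list(
    W0 = matrix(stats::rnorm(h * channels, sd = sqrt(2 / channels)), h, channels),
    W1 = matrix(stats::rnorm(channels * h, sd = sqrt(2 / h)), channels, h)
  ))
}

#' Create a spatial-attention gate
#'
#' A single-output-channel convolution over the concatenated channel-wise
#' mean and max maps; padding preserves the spatial dimensions.
#'
#' @param kernel Odd kernel size of the convolution (default 7).
#' @param seed Integer seed for weight initialization.
#' @return A list with the kernel array `W` (kernel x kernel x 2 x 1) and
#'   bias `b` (length 1).
#' @export
spatialGate <- function(kernel = 7L, seed = 1L) {
  stopifnot(kernel %% 2L == 1L)
  withSeed(seed, list(
    W = array(stats::rnorm(kernel * kernel * 2, sd = sqrt(2 / (kernel * kernel * 2))),
              c(kernel, kernel, 2L, 1L)),
    b = 0
  ))
}

#' Channel attention weights of a feature stack
#'
#' Computes sigmoid(MLP(avgpool(F)) + MLP(maxpool(F))) with one shared MLP:
#' the per-channel gating vector that rescales a feature stack.
#'
#' @param F An H x W x M feature array.
#' @param gate A [channelGate()] (list with `W0`, `W1`).
#' @return Numeric vector of length M with entries strictly in (0, 1).
#' @export
channelAttention <- function(F, gate) {
  F <- as4d(F)
  stopifnotFinite(F, "feature maps")
  as.vector(cgF(F, gate$W0, gate$W1)$weights)
}

#' Spatial attention map of a feature stack
#'
#' Concatenates the channel-wise mean and max maps, convolves them to a
#' single channel and applies a sigmoid, yielding one weight per spatial
#' position.
#'
#' @param F An H x W x M feature array (typically already channel-refined).
#' @param gate A [spatialGate()].
#' @return An H x W matrix with entries strictly in (0, 1).
#' @export
spatialAttention <- function(F, gate) {
  F <- as4d(F)
  stopifnotFinite(F, "feature maps")
  sg <- sgF(F, gate$W, gate$b)
  matrix(sg$S, dim(F)[1L], dim(F)[2L])
}

#' Channel-then-spatial attention gating of a feature stack
#'
#' Applies the channel gate (each channel rescaled by its attention weight)
#' followed by the spatial gate (each position rescaled by its attention
#' weight). With both gates in (0, 1) the output never exceeds the input in
#' magnitude.
#'
#' @param F An H x W x M feature array.
#' @param cg A [channelGate()].
#' @param sg A [spatialGate()].
#' @param bypass If `TRUE`, both gates are clamped to 1 and `F` is returned
#'   unchanged (used for degenerate-configuration checks).
#' @return An H x W x M array of gated features.
#' @export
cbam <- function(F, cg, sg, bypass = FALSE) {
  F3 <- as4d(F)
  stopifnotFinite(F3, "feature maps")
  if (bypass) return(F)
  out <- sgF(cgF(F3, cg$W0, cg$W1)$y, sg$W, sg$b)$y
  array(out, dim(F3)[1:3])
}
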