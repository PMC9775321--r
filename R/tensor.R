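# Internal tensor primitives. Activation stacks are stored as 4D arrays
# [H, W, C, B] (rows, columns, channels, batch). Convolutions are computed
# by im2col lowering followed by a BLAS matrix multiply; every forward
# returns the cache its analytic backward needs. All backwards are verified
# against finite differences in the test suite.

as4d <- function(x) {
  if (is.matrix(x)) dim(x) <- c(dim(x), 1L, 1L)
  else if (length(dim(x)) == 3L) dim(x) <- c(dim(x), 1L)
  x
}

# Reshape [H,W,C,B] so channels index columns: returns (H*W*B) x C matrix.
chanMat <- function(x) {
  d <- dim(x)
  matrix(aperm(x, c(1L, 2L, 4L, 3L)), d[1L] * d[2L] * d[4L], d[3L])
}

chanArr <- function(m, d) {
  aperm(array(m, c(d[1L], d[2L], d[4L], d[3L])), c(1L, 2L, 4L, 3L))
}

im2col <- function(x, kh, kw, stride, pad) {
  d <- dim(x)
  H <- d[1L]; W <- d[2L]; C <- d[3L]; B <- d[4L]
  Ho <- (H + 2L * pad - kh) %/% stride + 1L
  Wo <- (W + 2L * pad - kw) %/% stride + 1L
  xp <- x
  if (pad > 0L) {
    xp <- array(0, c(H + 2L * pad, W + 2L * pad, C, B))
    xp[pad + seq_len(H), pad + seq_len(W), , ] <- x
  }
  cols <- matrix(0, Ho * Wo * B, kh * kw * C)
  ri <- seq.int(0L, Ho - 1L) * stride
  ci <- seq.int(0L, Wo - 1L) * stride
  q <- 0L
  for (cc in seq_len(C)) for (j in seq_len(kw)) for (i in seq_len(kh)) {
    q <- q + 1L
    cols[, q] <- as.vector(xp[i + ri, j + ci, cc, ])
  }
  list(cols = cols, Ho = Ho, Wo = Wo)
}

convF <- function(x, W, b = NULL, stride = 1L, pad = 0L) {
  kd <- dim(W)
  ic <- im2col(x, kd[1L], kd[2L], stride, pad)
  Wm <- matrix(W, kd[1L] * kd[2L] * kd[3L], kd[4L])
  ym <- ic$cols %*% Wm
  if (!is.null(b)) ym <- ym + rep(b, each = nrow(ym))
  B <- dim(x)[4L]
  y <- aperm(array(ym, c(ic$Ho, ic$Wo, B, kd[4L])), c(1L, 2L, 4L, 3L))
  list(y = y,
       cache = list(cols = ic$cols, xdim = dim(x), Wdim = kd,
                    stride = stride, pad = pad, hasb = !is.null(b)))
}

convB <- function(dy, W, cache) {
  kd <- cache$Wdim
  kh <- kd[1L]; kw <- kd[2L]; Cin <- kd[3L]; Cout <- kd[4L]
  d <- dim(dy)
  Ho <- d[1L]; Wo <- d[2L]; B <- d[4L]
  dym <- matrix(aperm(dy, c(1L, 2L, 4L, 3L)), Ho * Wo * B, Cout)
  dW <- array(crossprod(cache$cols, dym), dim = kd)
  db <- if (cache$hasb) colSums(dym) else NULL
  dcols <- tcrossprod(dym, matrix(W, kh * kw * Cin, Cout))
  xd <- cache$xdim
  H <- xd[1L]; Wd <- xd[2L]; C <- xd[3L]
  pad <- cache$pad; stride <- cache$stride
  gp <- array(0, c(H + 2L * pad, Wd + 2L * pad, C, B))
  ri <- seq.int(0L, Ho - 1L) * stride
  ci <- seq.int(0L, Wo - 1L) * stride
  q <- 0L
  for (cc in seq_len(C)) for (j in seq_len(kw)) for (i in seq_len(kh)) {
    q <- q + 1L
    gp[i + ri, j + ci, cc, ] <- gp[i + ri, j + ci, cc, ] + dcols[, q]
  }
  dx <- if (pad > 0L)
    gp[pad + seq_len(H), pad + seq_len(Wd), , , drop = FALSE]
  else gp
  list(dx = dx, dW = dW, db = db)
}

# Batch normalization over (H, W, B) per channel.
bnF <- function(x, g, b, rm, rv, train, momentum = 0.1, eps = 1e-5) {
  d <- dim(x)
  xm <- chanMat(x)
  if (train) {
    mu <- colMeans(xm)
    xc <- sweep(xm, 2L, mu)
    v <- colMeans(xc * xc)
    n <- nrow(xm)
    rm <- (1 - momentum) * rm + momentum * mu
    rv <- (1 - momentum) * rv + momentum * v * n / max(1, n - 1)
  } else {
    mu <- rm
    v <- rv
    xc <- sweep(xm, 2L, mu)
  }
  istd <- 1 / sqrt(v + eps)
  xh <- sweep(xc, 2L, istd, "*")
  ym <- sweep(sweep(xh, 2L, g, "*"), 2L, b, "+")
  list(y = chanArr(ym, d),
       cache = list(xh = xh, istd = istd, g = g, d = d, train = train),
       rm = rm, rv = rv)
}

bnB <- function(dy, cache) {
  d <- cache$d
  dym <- chanMat(dy)
  dg <- colSums(dym * cache$xh)
  db <- colSums(dym)
  dxh <- sweep(dym, 2L, cache$g, "*")
  if (cache$train) {
    t1 <- sweep(dxh, 2L, colMeans(dxh))
    t2 <- sweep(cache$xh, 2L, colMeans(dxh * cache$xh), "*")
    dxm <- sweep(t1 - t2, 2L, cache$istd, "*")
  } else {
    dxm <- sweep(dxh, 2L, cache$istd, "*")
  }
  list(dx = chanArr(dxm, d), dg = dg, db = db)
}

reluF <- function(x) {
  m <- x > 0
  list(y = x * m, mask = m)
}

reluB <- function(dy, mask) dy * mask

maxPoolF <- function(x, k, stride, pad = 0L) {
  d <- dim(x)
  H <- d[1L]; W <- d[2L]; C <- d[3L]; B <- d[4L]
  Ho <- (H + 2L * pad - k) %/% stride + 1L
  Wo <- (W + 2L * pad - k) %/% stride + 1L
  xp <- x
  if (pad > 0L) {
    xp <- array(-Inf, c(H + 2L * pad, W + 2L * pad, C, B))
    xp[pad + seq_len(H), pad + seq_len(W), , ] <- x
  }
  ri <- seq.int(0L, Ho - 1L) * stride
  ci <- seq.int(0L, Wo - 1L) * stride
  y <- array(-Inf, c(Ho, Wo, C, B))
  arg <- array(0L, c(Ho, Wo, C, B))
  q <- 0L
  for (j in seq_len(k)) for (i in seq_len(k)) {
    q <- q + 1L
    cand <- xp[i + ri, j + ci, , , drop = FALSE]
    upd <- cand > y
    y[upd] <- cand[upd]
    arg[upd] <- q
  }
  list(y = y, cache = list(arg = arg, xdim = d, k = k, stride = stride,
                           pad = pad, Ho = Ho, Wo = Wo))
}

maxPoolB <- function(dy, cache) {
  d <- cache$xdim
  pad <- cache$pad; stride <- cache$stride; k <- cache$k
  gp <- array(0, c(d[1L] + 2L * pad, d[2L] + 2L * pad, d[3L], d[4L]))
  ri <- seq.int(0L, cache$Ho - 1L) * stride
  ci <- seq.int(0L, cache$Wo - 1L) * stride
  q <- 0L
  for (j in seq_len(k)) for (i in seq_len(k)) {
    q <- q + 1L
    sel <- cache$arg == q
    if (!any(sel)) next
    blk <- gp[i + ri, j + ci, , , drop = FALSE]
    blk[sel] <- blk[sel] + dy[sel]
    gp[i + ri, j + ci, , ] <- blk
  }
  if (pad > 0L)
    gp[pad + seq_len(d[1L]), pad + seq_len(d[2L]), , , drop = FALSE]
  else gp
}
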