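# Independent brute-force oracles used across the suite. These deliberately
# use naive loops (no im2col, no vectorized pooling) so they share no code
# path with the implementation they check.

sigmoidRef <- function(x) 1 / (1 + exp(-x))

# Naive sliding-window 2D convolution of an H x W x Cin array with a
# kh x kw x Cin x Cout kernel (stride 1, symmetric zero padding).
bruteConv <- function(x, W, b = NULL, pad = 0L) {
  d <- dim(x)
  kd <- dim(W)
  H <- d[1L]; Wd <- d[2L]; Cin <- d[3L]
  xp <- array(0, c(H + 2L * pad, Wd + 2L * pad, Cin))
  xp[pad + seq_len(H), pad + seq_len(Wd), ] <- x
  Ho <- H + 2L * pad - kd[1L] + 1L
  Wo <- Wd + 2L * pad - kd[2L] + 1L
  out <- array(0, c(Ho, Wo, kd[4L]))
  for (o in seq_len(kd[4L])) for (i in seq_len(Ho)) for (j in seq_len(Wo)) {
    s <- 0
    for (c in seq_len(Cin)) for (a in seq_len(kd[1L])) for (bb in seq_len(kd[2L]))
      s <- s + xp[i + a - 1L, j + bb - 1L, c] * W[a, bb, c, o]
    out[i, j, o] <- s + if (is.null(b)) 0 else b[o]
  }
  out
}

# Channel attention by direct arithmetic on an H x W x M array.
bruteChannelAttention <- function(F, W0, W1) {
  M <- dim(F)[3L]
  avg <- numeric(M)
  mx <- numeric(M)
  for (m in seq_len(M)) {
    avg[m] <- mean(F[, , m])
    mx[m] <- max(F[, , m])
  }
  mlp <- function(v) as.vector(W1 %*% pmax(W0 %*% v, 0))
  sigmoidRef(mlp(avg) + mlp(mx))
}

# Spatial attention by direct arithmetic.
bruteSpatialAttention <- function(F, W, b) {
  d <- dim(F)
  st <- array(0, c(d[1L], d[2L], 2L))
  for (i in seq_len(d[1L])) for (j in seq_len(d[2L])) {
    st[i, j, 1L] <- mean(F[i, j, ])
    st[i, j, 2L] <- max(F[i, j, ])
  }
  pad <- (dim(W)[1L] - 1L) %/% 2L
  sigmoidRef(bruteConv(st, W, b, pad = pad)[, , 1L])
}

bruteCbam <- function(F, cg, sg) {
  mc <- bruteChannelAttention(F, cg$W0, cg$W1)
  Fp <- F
  for (m in seq_len(dim(F)[3L])) Fp[, , m] <- F[, , m] * mc[m]
  ms <- bruteSpatialAttention(Fp, sg$W, sg$b)
  Fpp <- Fp
  for (m in seq_len(dim(F)[3L])) Fpp[, , m] <- Fp[, , m] * ms
  Fpp
}

# Triple-loop bilinear attention pooling.
bruteBap <- function(F, A) {
  N <- dim(A)[3L]
  M <- dim(F)[3L]
  P <- matrix(0, N, M)
  for (i in seq_len(N)) for (m in seq_len(M))
    P[i, m] <- mean(A[, , i] * F[, , m])
  P
}

# Plain bottleneck residual block (no attention gates), evaluation-mode
# batch norm written out longhand.
brutePlainBlock <- function(X, p, st, stride) {
  bnEval <- function(x, g, b, rm, rv, eps = 1e-5) {
    out <- x
    for (c in seq_len(dim(x)[3L]))
      out[, , c] <- (x[, , c] - rm[c]) / sqrt(rv[c] + eps) * g[c] + b[c]
    out
  }
  convStride <- function(x, W, stride, pad) {
    full <- bruteConv(x, W, pad = pad)
    ri <- seq(1L, dim(full)[1L], by = stride)
    ci <- seq(1L, dim(full)[2L], by = stride)
    full[ri, ci, , drop = FALSE]
  }
  h <- pmax(bnEval(bruteConv(X, p$W1), p$g1, p$b1, st$rm1, st$rv1), 0)
  h <- pmax(bnEval(convStride(h, p$W2, stride, 1L), p$g2, p$b2, st$rm2, st$rv2), 0)
  h <- bnEval(bruteConv(h, p$W3), p$g3, p$b3, st$rm3, st$rv3)
  sc <- if (!is.null(p$pW))
    bnEval(convStride(X, p$pW, stride, 0L), p$pg, p$pb, st$prm, st$prv)
  else X
  sc + h
}

# Small random feature stack helper.
randArray <- function(dims, seed) {
  set.seed(seed)
  array(stats::rnorm(prod(dims)), dims)
}
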