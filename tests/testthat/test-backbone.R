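test_that("channel attention follows the shared-MLP sigmoid form", {
  F <- randArray(c(4, 4, 3), seed = 1)
  # zero MLP weights: sigmoid(0) = 0.5 per channel
  gate0 <- list(W0 = matrix(0, 2, 3), W1 = matrix(0, 3, 2))
  expect_equal(channelAttention(F, gate0), rep(0.5, 3))
  # any input: strictly inside (0, 1)
  gate <- channelGate(3, reduction = 2, seed = 11)
  w <- channelAttention(F, gate)
  expect_true(all(w > 0 & w < 1))
  # spatially constant stack: avg pool equals max pool, Mc = sigmoid(2 MLP(v))
  v <- c(0.3, -1.2, 2.0)
  Fc <- array(rep(v, each = 16), c(4, 4, 3))
  W0 <- matrix(c(0.5, -0.2, 0.1, 0.4, -0.3, 0.2), 2, 3)
  W1 <- matrix(c(1, 0.5, -1, 0.2, 0.3, -0.4), 3, 2)
  manual <- 1 / (1 + exp(-(2 * as.vector(W1 %*% pmax(W0 %*% v, 0)))))
  expect_equal(channelAttention(Fc, list(W0 = W0, W1 = W1)), manual,
               tolerance = 1e-12)
})

test_that("spatial attention matches a sliding-window convolution oracle", {
  gate0 <- list(W = array(0, c(7, 7, 2, 1)), b = 0)
  F <- randArray(c(5, 5, 3), seed = 2)
  expect_equal(spatialAttention(F, gate0), matrix(0.5, 5, 5))
  # constant across channels: mean map equals max map
  Fc <- array(rep(randArray(c(5, 5, 1), 3), 3), c(5, 5, 3))
  gate <- spatialGate(7L, seed = 4)
  sPkg <- spatialAttention(Fc, gate)
  sRef <- bruteSpatialAttention(Fc, gate$W, gate$b)
  expect_equal(sPkg, sRef, tolerance = 1e-9)
  # random input, fixed-seed kernel, against the brute-force convolution
  expect_equal(spatialAttention(F, gate),
               bruteSpatialAttention(F, gate$W, gate$b), tolerance = 1e-9)
})

test_that("the combined gate composes channel then spatial attention", {
  F <- randArray(c(2, 2, 2), seed = 5)
  cg <- channelGate(2, reduction = 2, seed = 6)
  sg <- spatialGate(7L, seed = 7)
  expect_equal(cbam(F, cg, sg), bruteCbam(F, cg, sg), tolerance = 1e-9)
  # bypass mode is the identity; zero input stays zero
  expect_identical(cbam(F, cg, sg, bypass = TRUE), F)
  expect_equal(cbam(array(0, c(2, 2, 2)), cg, sg), array(0, c(2, 2, 2)))
})

test_that("gating never increases activation magnitude", {
  for (s in 1:5) {
    F <- randArray(c(3, 4, 5), seed = 100 + s)
    cg <- channelGate(5, seed = s)
    sg <- spatialGate(7L, seed = s + 50)
    out <- cbam(F, cg, sg)
    expect_true(all(abs(out) <= abs(F) + 1e-12))
  }
})

test_that("the gated residual block reduces to its parts in degenerate modes", {
  blk <- improvedBlock(3L, 2L, 5L, stride = 1L, seed = 8)
  X <- randArray(c(6, 6, 3), seed = 9)
  # residual forced to zero: output equals the (projected) shortcut; with
  # the final batch-norm scale zeroed the gated residual vanishes
  blk0 <- blk
  blk0$params$g3 <- rep(0, 5L)
  blk0$params$b3 <- rep(0, 5L)
  out0 <- improvedBlockForward(X, blk0, bypass = TRUE)
  proj <- bruteConv(X, blk$params$pW)
  projBn <- proj
  for (c in 1:5) projBn[, , c] <- (proj[, , c] - blk$state$prm[c]) /
    sqrt(blk$state$prv[c] + 1e-5) * blk$params$pg[c] + blk$params$pb[c]
  expect_equal(out0, projBn, tolerance = 1e-9)
  # identity shortcut variant: zero residual returns X exactly
  blkI <- improvedBlock(4L, 2L, 4L, stride = 1L, seed = 10)
  blkI$params$g3 <- rep(0, 4L)
  XI <- randArray(c(5, 5, 4), seed = 11)
  expect_equal(improvedBlockForward(XI, blkI, bypass = TRUE), XI,
               tolerance = 1e-12)
  expect_error(improvedBlockForward(randArray(c(4, 4, 7), 1), blk), "channels")
})

test_that("bypassed gates reproduce a plain bottleneck block exactly", {
  for (s in 1:3) {
    blk <- improvedBlock(3L, 2L, 6L, stride = 2L, seed = 20 + s)
    X <- randArray(c(7, 7, 3), seed = 30 + s)
    got <- improvedBlockForward(X, blk, bypass = TRUE)
    ref <- brutePlainBlock(X, blk$params, blk$state, 2L)
    expect_equal(got, ref, tolerance = 1e-9)
  }
})

test_that("full step-by-step evaluation matches the gated block forward", {
  # layer-by-layer oracle: plain bottleneck then the two gates on the
  # residual, then the shortcut addition
  blk <- improvedBlock(4L, 2L, 4L, stride = 1L, seed = 41)
  X <- randArray(c(4, 4, 4), seed = 42)
  got <- improvedBlockForward(X, blk)
  residPlain <- brutePlainBlock(X, blk$params, blk$state, 1L) - X
  gated <- bruteCbam(residPlain,
                     list(W0 = blk$params$cgW0, W1 = blk$params$cgW1),
                     list(W = blk$params$sgW, b = blk$params$sgb))
  expect_equal(got, X + gated, tolerance = 1e-9)
})

test_that("backbone shapes, determinism and stage layout are as configured", {
  m <- buildBackbone("tiny", inputSize = c(64L, 64L), nMaps = 4L, seed = 3L)
  img <- matrix(runif(64 * 64), 64, 64)
  F <- extractFeatures(m, img)
  expect_equal(dim(F), c(8L, 8L, 32L))   # 64 / (2*2*2), 32 channels
  m2 <- buildBackbone("tiny", inputSize = c(64L, 64L), nMaps = 4L, seed = 3L)
  expect_identical(m@params, m2@params)
  m3 <- buildBackbone("tiny", inputSize = c(64L, 64L), nMaps = 4L, seed = 4L)
  expect_false(identical(m@params, m3@params))
  expect_lt(countParams(m), 100000L)
  # standard 50-layer stage layout: 3+4+6+3 gated bottleneck blocks
  r50 <- buildBackbone("resnet50", inputSize = c(224L, 224L))
  expect_length(modelConfig(r50)$blocks, 16L)
  expect_equal(vapply(modelConfig(r50)$blocks, `[[`, 1L, "cout"),
               rep(c(256L, 512L, 1024L, 2048L), c(3L, 4L, 6L, 3L)))
  expect_error(buildBackbone("tiny", pretrained = TRUE), "pretrained")
  expect_error(buildBackbone("vgg"), "should be one of")
})

test_that("the residual path passes gradients through the identity branch", {
  # finite differences on the scalar loss sum(sin(output)) of a tiny block:
  # the input gradient must contain the identity path even when the
  # residual branch is suppressed
  ns <- asNamespace("wsattn")
  blk <- improvedBlock(2L, 1L, 2L, stride = 1L, seed = 55)
  X <- randArray(c(3, 3, 2, 1), seed = 56)
  fwd <- ns$blockF(X, blk$params, blk$state, 1L, train = FALSE, bypass = FALSE)
  dy <- cos(fwd$y)
  bk <- ns$blockB(dy, blk$params, fwd$cache)
  num <- array(0, dim(X))
  eps <- 1e-6
  for (i in seq_along(X)) {
    Xp <- X; Xp[i] <- Xp[i] + eps
    Xm <- X; Xm[i] <- Xm[i] - eps
    num[i] <- (sum(sin(ns$blockF(Xp, blk$params, blk$state, 1L, FALSE, FALSE)$y)) -
               sum(sin(ns$blockF(Xm, blk$params, blk$state, 1L, FALSE, FALSE)$y))) /
              (2 * eps)
  }
  expect_equal(bk$dx, num, tolerance = 1e-6)
  # suppress the residual entirely: gradient reduces to the identity path
  blk0 <- blk
  blk0$params$g3 <- rep(0, 2L)
  fwd0 <- ns$blockF(X, blk0$params, blk0$state, 1L, FALSE, TRUE)
  bk0 <- ns$blockB(cos(fwd0$y), blk0$params, fwd0$cache)
  expect_equal(bk0$dx, cos(X), tolerance = 1e-9)
})
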