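test_that("probability fusion averages, preserves normalization, commutes", {
  expect_equal(fuseProbabilities(c(0.3, 0.7), c(0.3, 0.7)), c(0.3, 0.7))
  expect_equal(fuseProbabilities(c(1, 0), c(0, 1)), c(0.5, 0.5))
  set.seed(1)
  for (rep in 1:10) {
    a <- runif(2); a <- a / sum(a)
    b <- runif(2); b <- b / sum(b)
    expect_equal(sum(fuseProbabilities(a, b)), 1, tolerance = 1e-12)
    expect_equal(fuseProbabilities(a, b), fuseProbabilities(b, a))
  }
  expect_error(fuseProbabilities(c(1, 0), c(1, 0, 0)), "length")
})

test_that("confusion tallies match a direct counting loop", {
  cc <- confusionCounts(c("positive", "positive", "negative", "negative"),
                        c("positive", "negative", "negative", "positive"))
  expect_equal(asCounts(cc), c(TP = 1L, FP = 1L, TN = 1L, FN = 1L))
  ccAll <- confusionCounts(rep("positive", 5), rep("positive", 5))
  expect_equal(asCounts(ccAll)[["FP"]], 0L)
  expect_equal(asCounts(ccAll)[["FN"]], 0L)
  set.seed(2)
  lab <- sample(c("positive", "negative"), 100, replace = TRUE)
  pred <- sample(c("positive", "negative"), 100, replace = TRUE)
  cc2 <- confusionCounts(lab, pred)
  ref <- c(TP = 0L, FP = 0L, TN = 0L, FN = 0L)
  for (i in 1:100) {
    if (lab[i] == "positive" && pred[i] == "positive") ref["TP"] <- ref["TP"] + 1L
    if (lab[i] == "negative" && pred[i] == "positive") ref["FP"] <- ref["FP"] + 1L
    if (lab[i] == "negative" && pred[i] == "negative") ref["TN"] <- ref["TN"] + 1L
    if (lab[i] == "positive" && pred[i] == "negative") ref["FN"] <- ref["FN"] + 1L
  }
  expect_equal(asCounts(cc2), ref)
  expect_error(confusionCounts(character(0), character(0)), "no samples")
  expect_error(confusionCounts(lab, pred[1:99]), "length")
})

test_that("the five screening metrics follow their printed formulas", {
  perfect <- methods::new("ConfusionCounts", tp = 50L, fp = 0L, tn = 50L,
                          fn = 0L)
  expect_equal(unname(classificationMetrics(perfect)), rep(1, 5))
  cc <- methods::new("ConfusionCounts", tp = 40L, fp = 5L, tn = 45L,
                     fn = 10L)
  m <- classificationMetrics(cc)
  expect_equal(m[["sensitivity"]], 0.8)
  expect_equal(m[["specificity"]], 0.9)
  expect_equal(m[["precision"]], 40 / 45)
  expect_equal(m[["accuracy"]], 0.85)
  expect_equal(m[["f1"]], 80 / 95)
  # percentage rendering mirrors the usual table format
  mp <- classificationMetrics(cc, percent = TRUE)
  expect_equal(mp[["precision"]], 88.89)
  expect_equal(mp[["f1"]], 84.21)
  # undefined metrics are flagged, not zeroed
  noPos <- methods::new("ConfusionCounts", tp = 0L, fp = 0L, tn = 10L,
                        fn = 0L)
  mu <- classificationMetrics(noPos)
  expect_true(is.na(mu[["precision"]]))
  expect_true("precision" %in% attr(mu, "undefined"))
  expect_false(is.na(mu[["specificity"]]))
})

test_that("accuracy and F1 satisfy their algebraic identities", {
  set.seed(3)
  for (rep in 1:30) {
    v <- as.integer(rmultinom(1, 40, rep(0.25, 4)))
    cc <- methods::new("ConfusionCounts", tp = v[1], fp = v[2], tn = v[3],
                       fn = v[4])
    m <- classificationMetrics(cc)
    # balanced classes: accuracy between sensitivity and specificity
    if (v[1] + v[4] == v[2] + v[3] && !anyNA(m[c("sensitivity", "specificity")])) {
      expect_gte(m[["accuracy"]], min(m[["sensitivity"]], m[["specificity"]]) - 1e-12)
      expect_lte(m[["accuracy"]], max(m[["sensitivity"]], m[["specificity"]]) + 1e-12)
    }
    # F1 is the harmonic mean of precision and sensitivity when defined
    if (!anyNA(m[c("precision", "sensitivity")]) &&
        m[["precision"]] + m[["sensitivity"]] > 0) {
      hm <- 2 * m[["precision"]] * m[["sensitivity"]] /
        (m[["precision"]] + m[["sensitivity"]])
      expect_equal(m[["f1"]], hm, tolerance = 1e-12)
    }
  }
})

test_that("coarse inference is deterministic and sums to one", {
  model <- buildBackbone("tiny", nMaps = 3L, seed = 12L)
  img <- matrix(runif(32 * 32), 32, 32)
  p1 <- predictCoarse(model, img)
  p2 <- predictCoarse(model, img)
  expect_identical(p1, p2)
  expect_equal(sum(p1), 1, tolerance = 1e-6)
  expect_named(p1, c("negative", "positive"))
  # zero classifier head: uniform probabilities
  m0 <- model
  m0@params$headW[] <- 0
  m0@params$headB[] <- 0
  expect_equal(unname(predictCoarse(m0, img)), c(0.5, 0.5), tolerance = 1e-12)
})

test_that("fine inference crops where attention concentrates", {
  model <- buildBackbone("tiny", nMaps = 3L, seed = 13L)
  img <- matrix(runif(32 * 32), 32, 32)
  pf <- predictFine(model, img, thetaTest = 0.6)
  box <- attr(pf, "box")
  expect_equal(sum(pf), 1, tolerance = 1e-6)
  # the fine pass must agree with coarse prediction on the external crop
  A <- attentionMaps(model, img)
  Anorm <- normalizeAttention(apply(A, c(1, 2), sum))
  cm <- cropMask(Anorm, 0.6, warn = FALSE)
  crop <- applyCrop(img, cm$box, c(32L, 32L), gridSize = dim(Anorm))
  expect_equal(unname(as.vector(pf)), unname(predictCoarse(model, crop)),
               tolerance = 1e-12)
  # flat attention: fallback makes fine equal coarse exactly
  mFlat <- model
  mFlat@params$attnW[] <- 0
  mFlat@params$attnB[] <- 0
  pfF <- predictFine(mFlat, img)
  expect_equal(unname(as.vector(pfF)), unname(predictCoarse(mFlat, img)),
               tolerance = 1e-15)
  expect_equal(attr(pfF, "box"), c(0L, nrow(Anorm), 0L, ncol(Anorm)))
})
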