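test_that("selection fitness matches hand arithmetic", {
  expect_equal(selectionFitness(c(tp = 1, tn = 1, fp = 0, fn = 0)), 1)
  expect_equal(selectionFitness(c(tp = 1, tn = 1, fp = 1, fn = 1)), 0)
  expect_equal(selectionFitness(c(tp = 50, tn = 40, fp = 5, fn = 5)),
               1975 / 6125625, tolerance = 1e-12)
  expect_warning(
    expect_equal(selectionFitness(c(tp = 0, tn = 5, fp = 0, fn = 0)), 0),
    "marginal")
})

test_that("selection fitness is antisymmetric under prediction inversion", {
  set.seed(61)
  for (k in 1:10) {
    c0 <- c(tp = sample(1:50, 1), tn = sample(1:50, 1),
            fp = sample(1:50, 1), fn = sample(1:50, 1))
    flipped <- c(tp = c0[["fp"]], tn = c0[["fn"]],
                 fp = c0[["tp"]], fn = c0[["tn"]])
    expect_equal(selectionFitness(flipped), -selectionFitness(c0),
                 tolerance = 1e-12)
  }
})

test_that("binarization thresholds at 0.5 with a non-empty fallback", {
  expect_equal(binarizeSolution(c(0.9, 0.1, 0.6)), c(TRUE, FALSE, TRUE))
  z <- binarizeSolution(c(0, 0, 0))
  expect_equal(sum(z), 1L)
  expect_true(z[1])
  v <- c(TRUE, FALSE, TRUE)
  expect_equal(binarizeSolution(as.numeric(v)), v)
})

test_that("metric report matches hand-derived confusion arithmetic", {
  p <- countsToLabels(tp = 8, tn = 7, fp = 1, fn = 4)
  m <- evaluateMetrics(p$yTrue, p$yPred)
  expect_equal(m$acc, 75)
  expect_equal(m$f1, 16 / 21, tolerance = 1e-12)
  expect_equal(m$ppv, m$pr / 100, tolerance = 1e-12)

  p2 <- countsToLabels(tp = 45, tn = 45, fp = 5, fn = 5)
  m2 <- evaluateMetrics(p2$yTrue, p2$yPred)
  expect_equal(m2$mcc, 0.8, tolerance = 1e-12)

  perfect <- countsToLabels(tp = 5, tn = 5, fp = 0, fn = 0)
  mp <- evaluateMetrics(perfect$yTrue, perfect$yPred)
  expect_equal(mp$acc, 100)
  expect_equal(mp$f1, 1)
  expect_equal(mp$mcc, 1)
  expect_error(evaluateMetrics(factor(), factor()), "empty")
})

test_that("metrics agree with a brute-force recount on random labels", {
  set.seed(62)
  for (k in 1:10) {
    yT <- factor(sample(c("benign", "malignant"), 40, TRUE),
                 levels = c("benign", "malignant"))
    yP <- factor(sample(c("benign", "malignant"), 40, TRUE),
                 levels = c("benign", "malignant"))
    cc <- confusionCounts(yT, yP)
    brute <- c(tp = 0, tn = 0, fp = 0, fn = 0)
    for (i in seq_along(yT)) {
      truthPos <- yT[i] == "malignant"
      predPos <- yP[i] == "malignant"
      key <- if (truthPos && predPos) "tp" else if (!truthPos && !predPos)
        "tn" else if (predPos) "fp" else "fn"
      brute[key] <- brute[key] + 1
    }
    expect_equal(cc, brute)
    m <- evaluateMetrics(yT, yP)
    expect_equal(m$acc, 100 * (brute[["tp"]] + brute[["tn"]]) / 40)
  }
})

test_that("SVM kernels show the classic separability pattern", {
  blobs <- makeBlobs(seed = 3)
  m <- trainSvm(blobs$X, blobs$y, kernel = "linear")
  expect_equal(mean(predict(m, blobs$X) == blobs$y), 1)
  expect_identical(predict(m, blobs$X), predict(m, blobs$X))

  xo <- makeXor(seed = 4)
  ml <- trainSvm(xo$X, xo$y, kernel = "linear")
  expect_lte(mean(predict(ml, xo$X) == xo$y), 0.75)
  mr <- trainSvm(xo$X, xo$y, kernel = "rbf")
  expect_gte(mean(predict(mr, xo$X) == xo$y), 0.95)

  expect_error(trainSvm(cbind(c(NA, 1), c(1, 2)), factor(c("a", "b"))),
               "NA")
  expect_error(trainSvm(blobs$X, factor(rep("a", nrow(blobs$X)))),
               "two classes")
})

test_that("wrapper selection is deterministic and recovers planted features", {
  d <- generateFeatureTable(nSamples = 100, nInformative = 2,
                            effectSize = 2, seed = 71)
  s1 <- selectFeatures(d$features, d$labels, nPop = 12, maxIter = 15,
                       seed = 5)
  s2 <- selectFeatures(d$features, d$labels, nPop = 12, maxIter = 15,
                       seed = 5)
  expect_identical(s1$selected, s2$selected)
  expect_true(all(d$informative %in% which(s1$selected)))
  expect_gte(sum(s1$selected), 1L)
  idx <- c(1:5, 96:100)   # both classes present but too few samples
  expect_error(selectFeatures(d$features[idx, ], d$labels[idx]),
               "20 samples")
})

test_that("pure-noise tables score near the permutation null", {
  d <- generateFeatureTable(nSamples = 80, nInformative = 0,
                            effectSize = 0, seed = 72)
  obs <- crossValFitness(d$features, d$labels, folds = 5, seed = 2)$fitness
  # permutation null for the pooled-CV fitness
  null <- vapply(1:30, function(k) {
    set.seed(500 + k)
    crossValFitness(d$features, sample(d$labels), folds = 5,
                    seed = 2)$fitness
  }, numeric(1))
  expect_lte(abs(obs), stats::quantile(abs(null), 0.95) + 1e-6)
})

test_that("optimizer-tuned SVM is competitive with a grid-search oracle", {
  blobs <- makeBlobs(n = 60, sep = 4, seed = 8)
  tuned <- tuneSvm(blobs$X, blobs$y, kernel = "linear", nPop = 10,
                   maxIter = 12, seed = 3)
  expect_gte(tuned$cost, 1e-3)
  expect_lte(tuned$cost, 1e3)
  t2 <- tuneSvm(blobs$X, blobs$y, kernel = "linear", nPop = 10,
                maxIter = 12, seed = 3)
  expect_identical(tuned$cost, t2$cost)
  grid <- vapply(10^seq(-3, 3, length.out = 20), function(C)
    crossValFitness(blobs$X, blobs$y, cost = C, folds = 5,
                    seed = 3)$fitness, numeric(1))
  expect_gte(tuned$fitness, 0.9 * max(grid))
})
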