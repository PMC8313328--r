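test_that("SLIC on a uniform image degenerates to a regular spatial grid", {
  img <- array(128, c(64, 64, 3))
  lab <- slicSuperpixels(img, 16, compactness = 10, iterations = 5)
  K <- attr(lab, "K")
  expect_equal(K, 16L)
  expect_true(all(lab %in% 1:K))
  sizes <- table(lab)
  expect_equal(length(sizes), 16L)
  # near-equal Voronoi cells: every cell within a factor 2 of the mean
  expect_true(all(sizes > 64 * 64 / 16 / 2 & sizes < 64 * 64 / 16 * 2))
  expect_identical(slicSuperpixels(img, 16, 10, 5), lab)
  expect_error(slicSuperpixels(img, 64 * 64, 10), "superpixels")
})

test_that("SLIC labels are spatially connected with no empty label", {
  s <- generateLesion(lesionSpec(size = c(96L, 96L), a = 22, b = 17),
                      seed = 3)
  lab <- slicSuperpixels(lesionImage(s), 150)
  K <- attr(lab, "K")
  expect_true(all(tabulate(lab, K) > 0))
  # connectivity: per-label component count is 1
  set.seed(99)
  for (k in sample.int(K, 20)) {
    bin <- EBImage::bwlabel(EBImage::Image(t(lab == k)))
    expect_equal(max(bin), 1, label = sprintf("label %d connected", k))
  }
})

test_that("HSV histograms concentrate mass in the expected bins", {
  img <- array(0, c(12, 12, 3))
  img[, , 1] <- 255   # pure red
  lab <- matrix(1L, 12, 12); lab[, 7:12] <- 2L
  img[, 7:12, ] <- 0  # black block
  cf <- colorFeatures(img, lab)
  expect_equal(unname(cf[1, "h1"]), 1)   # hue of red = 0 -> first bin
  expect_equal(unname(cf[2, "v1"]), 1)   # black -> low value bin
  expect_equal(rowSums(cf[, 1:8]), c(1, 1), tolerance = 1e-9)
  expect_equal(rowSums(cf[, 9:12]), c(1, 1), tolerance = 1e-9)
  expect_equal(rowSums(cf[, 13:14]), c(1, 1), tolerance = 1e-9)
})

test_that("Gabor energies vanish on flat images and resolve grating orientation", {
  flat <- array(100, c(32, 32, 3))
  lab <- matrix(1L, 32, 32)
  tf <- textureFeatures(flat, lab)
  expect_true(all(tf >= 0))
  expect_true(all(tf < 1e-8))

  # vertical stripes: intensity varies along columns -> 0-degree filters
  g <- matrix(rep(c(0, 0, 255, 255), length.out = 32 * 32), 32, 32,
              byrow = TRUE)
  img <- array(rep(g, 3), c(32, 32, 3))
  tf <- textureFeatures(img, lab, wavelengths = 4)
  o <- colnames(tf)
  expect_equal(o[which.max(tf[1, ])], "gabor_w4_o0")
})

test_that("kernel fuzzy C-means separates blobs with normalized memberships", {
  set.seed(41)
  x <- rbind(matrix(rnorm(100), 50), matrix(rnorm(100) + 5, 50))
  kf <- kernelFuzzyCMeans(x, c = 2, seed = 2)
  expect_equal(colSums(kf$u), rep(1, 100), tolerance = 1e-9)
  expect_true(all(kf$u >= 0 & kf$u <= 1))
  hard <- apply(kf$u, 2, which.max)
  truth <- rep(1:2, each = 50)
  expect_gte(max(mean(hard == truth), mean(hard == 3 - truth)), 0.98)
  # objective non-increasing
  expect_true(all(diff(kf$objective) <= 1e-9))
  expect_error(kernelFuzzyCMeans(x[1:3, ], c = 5), "clusters")
})

test_that("affinity graph follows the neighbour / same-cluster / fuzzy-XOR rules", {
  # 6 points, two crisp clusters
  feats <- rbind(matrix(0, 3, 2) + rnorm(6, sd = 0.01),
                 matrix(5, 3, 2) + rnorm(6, sd = 0.01))
  u <- rbind(c(1, 1, 1, 0, 0, 0), c(0, 0, 0, 1, 1, 1))
  g <- buildAffinity(u, feats, tNeighbors = 2)
  expect_true(isSymmetric(g$W))
  expect_equal(g$W[1, 2], 1)         # same crisp cluster, neighbours
  expect_equal(g$W[1, 6], 0)         # not t-nearest neighbours
  expect_equal(g$D, rowSums(g$W))
  # crisp identical memberships give xor 0, so the formula branch is also 1
  u2 <- rbind(c(1, 1), c(0, 0))
  g2 <- buildAffinity(u2, matrix(c(0, 1), 2, 1), tNeighbors = 1)
  expect_equal(g2$W[1, 2], 1)
  expect_error(buildAffinity(u, feats, tNeighbors = 6), "smaller")
})

test_that("partially overlapping memberships attenuate the affinity by the fuzzy XOR", {
  # xor of (1,0) vs (0.45,0.55) = mean(0.55, 0.55) -> W = 2^(-0.55)
  u <- rbind(c(1, 0.45), c(0, 0.55))
  feats <- matrix(c(0, 0.1), 2, 1)
  g <- buildAffinity(u, feats, tNeighbors = 1)
  expect_equal(g$W[1, 2], 2^(-0.55), tolerance = 1e-9)
  # printed increasing variant, kept behind the flag
  gf <- buildAffinity(u, feats, tNeighbors = 1, flipSign = FALSE)
  expect_equal(gf$W[1, 2], 2^(0.55), tolerance = 1e-9)
})

test_that("spectral embedding matches a dense eigensolver oracle", {
  set.seed(43)
  for (rep in 1:3) {
    A <- matrix(runif(400), 20)
    W <- (A + t(A)) / 2
    diag(W) <- 1
    Y <- spectralEmbed(W, 3)
    expect_equal(sqrt(rowSums(Y^2)), rep(1, 20), tolerance = 1e-9)
    ev <- attr(Y, "values")
    expect_true(all(ev <= 1 + 1e-9 & ev >= -1 - 1e-9))
    # oracle: explicit diagonal-matrix products and a fresh eigensolve
    d <- rowSums(W)
    L <- diag(1 / sqrt(d)) %*% W %*% diag(1 / sqrt(d))
    eo <- eigen(L, symmetric = TRUE)
    expect_equal(ev[1:3], eo$values[1:3], tolerance = 1e-8)
    Y0 <- eo$vectors[, 1:3]
    Y0 <- Y0 / sqrt(rowSums(Y0^2))
    # eigenvectors are unique up to sign for distinct eigenvalues
    for (j in 1:3) if (sum(Y0[, j] * Y[, j]) < 0) Y0[, j] <- -Y0[, j]
    expect_lt(max(abs(Y - Y0)), 1e-6)
  }
})

test_that("block-diagonal affinity yields perfectly separable embeddings", {
  W <- matrix(0, 10, 10)
  W[1:5, 1:5] <- 0.8; W[6:10, 6:10] <- 0.8
  diag(W) <- 1
  Y <- spectralEmbed(W, 2)
  set.seed(44)
  cl <- kmeans(Y, 2, nstart = 5)$cluster
  expect_equal(length(unique(cl[1:5])), 1L)
  expect_equal(length(unique(cl[6:10])), 1L)
  expect_false(cl[1] == cl[6])
})

test_that("the full chain segments dark lesions accurately", {
  cfg <- segmentationConfig(seed = 1)
  batt <- generateLesionBattery(3, seed = 77)
  for (s in batt) {
    img <- stretchContrast(medianFilterImage(lesionImage(s)))
    mask <- segmentLesion(img, cfg)
    expect_true(all(mask %in% c(0L, 1L)))
    expect_equal(dim(mask), dim(lesionMask(s)))
    expect_gte(diceCoefficient(mask, lesionMask(s)), 0.85)
  }
})

test_that("polarity inversion with the central rule selects the same region", {
  s <- generateLesion(lesionSpec(saltPepperDensity = 0), seed = 21)
  img <- stretchContrast(medianFilterImage(lesionImage(s)))
  inv <- 255 - img
  cfg <- segmentationConfig(seed = 1, lesionRule = "central")
  mask <- segmentLesion(inv, cfg)
  expect_gte(diceCoefficient(mask, lesionMask(s)), 0.85)
})

test_that("dice coefficient behaves at the extremes", {
  a <- matrix(c(1, 1, 0, 0), 2)
  expect_equal(diceCoefficient(a, a), 1)
  expect_equal(diceCoefficient(a, 1 - a), 0)
  expect_equal(diceCoefficient(matrix(0, 2, 2), matrix(0, 2, 2)), 1)
})
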