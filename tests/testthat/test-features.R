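test_that("a rasterized disk measures as circular", {
  mask <- diskMask(20)
  img <- matrix(100, nrow(mask), ncol(mask)) + 20 * mask
  f <- extractFeatures(img, mask)
  expect_equal(f[["area"]], sum(mask))
  expect_gt(f[["irregularity_index"]], 0.95)
  expect_lt(f[["irregularity_index"]], 1.1)
  expect_lt(f[["eccentricity"]], 0.05)
  expect_gt(f[["solidity"]], 0.97)
  expect_lte(f[["solidity"]], 1 + 1e-9)
  expect_true(all(is.finite(f)) && all(f[c("form_factor", "rectangularity",
    "elongation_radius", "elongation_axis")] > 0))
})

test_that("axis-ratio ellipses give the derived eccentricity", {
  mask <- ellipseMask(30, 15)
  img <- matrix(100, nrow(mask), ncol(mask))
  f <- extractFeatures(img, mask)
  expect_equal(f[["eccentricity"]], sqrt(1 - 1 / 4), tolerance = 0.02)
})

test_that("moment invariants survive 90-degree rotation; all features survive translation", {
  s <- generateLesion(lesionSpec(a = 20, b = 14, irregularity = 0.1,
                                 saltPepperDensity = 0), seed = 6)
  mask <- lesionMask(s)
  gray <- matrix(80, nrow(mask), ncol(mask)) + 30 * mask
  f0 <- extractFeatures(gray, mask)
  # 90-degree rotation
  maskR <- t(mask)[ncol(mask):1, ]
  grayR <- t(gray)[ncol(gray):1, ]
  fR <- extractFeatures(grayR, maskR)
  expect_equal(f0[["hu_phi1"]], fR[["hu_phi1"]], tolerance = 1e-9)
  expect_equal(f0[["hu_phi2"]], fR[["hu_phi2"]], tolerance = 1e-9)
  expect_equal(f0[["hu_phi3"]], fR[["hu_phi3"]], tolerance = 1e-9)
  # translation by (3, 5) inside the canvas
  shift <- function(m, dr, dc, fill = 0) {
    out <- matrix(fill, nrow(m), ncol(m))
    out[(1 + dr):nrow(m), (1 + dc):ncol(m)] <-
      m[1:(nrow(m) - dr), 1:(ncol(m) - dc)]
    out
  }
  fT <- extractFeatures(shift(gray, 3, 5, fill = 80), shift(mask, 3, 5))
  expect_equal(fT, f0, tolerance = 1e-9)
})

test_that("constant-intensity regions have zero variance and unit energy", {
  mask <- diskMask(8)
  img <- matrix(200, nrow(mask), ncol(mask))
  f <- extractFeatures(img, mask)
  expect_equal(f[["variance"]], 0)
  expect_equal(f[["standard_deviation"]], 0)
  expect_equal(f[["energy"]], 1)     # one-hot co-occurrence matrix
  expect_equal(f[["entropy"]], 0)
})

test_that("the co-occurrence matrix is a normalized symmetric probability table", {
  set.seed(52)
  mask <- diskMask(10)
  img <- matrix(sample(0:255, length(mask), TRUE), nrow(mask))
  g <- computeGLCM(img, mask)
  expect_equal(sum(g$p), 1, tolerance = 1e-9)
  expect_true(all(g$p >= 0))
  expect_true(isSymmetric(unname(g$p)))
  expect_error(computeGLCM(img, mask * 0L), "empty")
})

test_that("uniform co-occurrence probabilities give entropy log(L^2)", {
  g <- structure(list(p = matrix(1 / 64, 8, 8), levels = 8L), class = "glcm")
  st <- glcmStatistics(g)
  expect_equal(st$entropy, log(64), tolerance = 1e-12)
  expect_equal(st$energy, 1 / 64, tolerance = 1e-12)
  expect_equal(st$correlation, 0, tolerance = 1e-12)  # independent marginals
})

test_that("solidity is 1 for convex masks", {
  rect <- matrix(0L, 20, 30); rect[5:15, 8:24] <- 1L
  img <- matrix(128, 20, 30)
  f <- extractFeatures(img, rect)
  expect_equal(f[["solidity"]], 1, tolerance = 1e-9)
})

test_that("degenerate masks are rejected with the feature named", {
  img <- matrix(100, 20, 20)
  thin <- matrix(0L, 20, 20); thin[10, 3:17] <- 1L
  expect_error(extractFeatures(img, thin), "eccentricity")
  small <- matrix(0L, 20, 20); small[10, 10] <- 1L
  expect_error(extractFeatures(img, small), "at least 10")
})

test_that("the printed constant compactness variant is available behind its flag", {
  mask <- diskMask(12)
  img <- matrix(100, nrow(mask), ncol(mask))
  f <- extractFeatures(img, mask, printedCompactness = TRUE)
  expect_equal(f[["compactness"]], 2 * pi)
  f2 <- extractFeatures(img, mask)
  expect_equal(f2[["compactness"]], 1 / f2[["irregularity_index"]],
               tolerance = 1e-9)
})
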