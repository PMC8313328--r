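## The 19 lesion descriptors: geometry and shape moments from the binary
## ROI mask, intensity statistics over in-mask pixels, and grey-level
## co-occurrence (GLCM) statistics.

#' Canonical names of the 19 lesion descriptors
#'
#' Two distinct elongation measures are kept (`elongation_radius`, based on
#' the maximal centroid-to-boundary radius, and `elongation_axis`, based on
#' the major axis) because both appear in the descriptor set.
#'
#' @return character vector of length 19.
#' @export
featureNames <- function() {
  c("elongation_radius", "elongation_axis", "area", "perimeter", "variance",
    "hu_phi1", "hu_phi2", "hu_phi3", "rectangularity", "irregularity_index",
    "form_factor", "compactness", "mean", "correlation", "solidity",
    "entropy", "eccentricity", "energy", "standard_deviation")
}

#' Grey-level co-occurrence matrix restricted to a mask
#'
#' In-mask intensities are quantized to `levels` equal-width bins between
#' the in-mask minimum and maximum; co-occurrences are counted only for
#' pixel pairs that both lie inside the mask, averaged over the offsets,
#' optionally symmetrized, and normalized to sum to 1.
#'
#' @param img image (converted to luminance).
#' @param mask binary 0/1 matrix.
#' @param levels number of grey levels.
#' @param offsets list of `c(dy, dx)` offsets.
#' @param symmetric logical; count each pair in both directions.
#' @return list of class `"glcm"` with `p` (levels x levels, sums to 1),
#'   `levels` and `offsets`.
#' @export
computeGLCM <- function(img, mask, levels = 8L,
                        offsets = list(c(0L, 1L), c(1L, 0L), c(1L, 1L),
                                       c(1L, -1L)),
                        symmetric = TRUE) {
  if (sum(mask) == 0) stop("empty mask")
  gray <- .toGray(img)
  inVals <- gray[mask == 1]
  lo <- min(inVals); hi <- max(inVals)
  q <- if (hi > lo) pmin(floor((gray - lo) / (hi - lo) * levels),
                         levels - 1L) + 1L
       else matrix(1L, nrow(gray), ncol(gray))
  h <- nrow(gray); w <- ncol(gray)
  p <- matrix(0, levels, levels)
  for (off in offsets) {
    dy <- off[1]; dx <- off[2]
    r0 <- max(1L, 1L - dy):min(h, h - dy)
    c0 <- max(1L, 1L - dx):min(w, w - dx)
    a <- q[r0, c0, drop = FALSE]
    b <- q[r0 + dy, c0 + dx, drop = FALSE]
    ok <- mask[r0, c0, drop = FALSE] == 1 &
      mask[r0 + dy, c0 + dx, drop = FALSE] == 1
    if (!any(ok)) next
    tab <- table(factor(a[ok], 1:levels), factor(b[ok], 1:levels))
    p <- p + matrix(as.numeric(tab), levels, levels)
  }
  if (symmetric) p <- p + t(p)
  if (sum(p) == 0) stop("mask too thin for the requested offsets")
  structure(list(p = p / sum(p), levels = levels, offsets = offsets),
            class = "glcm")
}

#' Energy, entropy and correlation of a co-occurrence matrix
#'
#' Energy is `sum(p^2)`; entropy is `-sum(p log p)` (natural log, with
#' `0 log 0 = 0`); correlation is the standard GLCM correlation
#' `(sum(i j p) - mu_r mu_c) / (sigma_r sigma_c)` over the row/column
#' marginal means and deviations.
#'
#' @param g a `"glcm"` object from [computeGLCM()].
#' @return list with `energy`, `entropy` and `correlation`.
#' @export
glcmStatistics <- function(g) .glcmStats(g)

.glcmStats <- function(g) {
  p <- g$p
  i <- seq_len(nrow(p))
  pr <- rowSums(p); pc <- colSums(p)
  muR <- sum(i * pr); muC <- sum(i * pc)
  sigR <- sqrt(sum((i - muR)^2 * pr)); sigC <- sqrt(sum((i - muC)^2 * pc))
  energy <- sum(p^2)
  pe <- p[p > 0]
  entropy <- -sum(pe * log(pe))
  correlation <- if (sigR > 0 && sigC > 0)
    (sum(outer(i, i) * p) - muR * muC) / (sigR * sigC) else 0
  list(energy = energy, entropy = entropy, correlation = correlation)
}

## Ordered outer boundary polygon of a mask (longest contour), traced with
## EBImage. The chain-code length (axial steps + sqrt(2) diagonal steps)
## systematically overestimates smooth boundaries by ~5%, so the
## Vossepoel-Smeulders corrected estimator is used when the contour is a
## proper 8-connected chain: 0.980 Ne + 1.406 No - 0.091 Nc, with Ne axial
## steps, No diagonal steps and Nc direction changes.
.contourPerimeter <- function(mask) {
  oc <- EBImage::ocontour(EBImage::Image(t(mask)))
  if (length(oc) == 0L) return(NA_real_)
  len <- vapply(oc, nrow, integer(1))
  pts <- oc[[which.max(len)]]
  if (nrow(pts) < 2L) return(4)     # single pixel
  dif <- rbind(diff(pts), pts[1, ] - pts[nrow(pts), ])
  stepLen <- sqrt(rowSums(dif^2))
  if (all(stepLen < 1.5)) {
    ne <- sum(stepLen < 1.2)
    no <- sum(stepLen >= 1.2)
    dir <- atan2(dif[, 2], dif[, 1])
    nc <- sum(dir != c(dir[-1], dir[1]))
    0.980 * ne + 1.406 * no - 0.091 * nc
  } else {
    sum(stepLen)
  }
}

.exposedEdges <- function(mask) {
  h <- nrow(mask); w <- ncol(mask)
  pad <- matrix(0L, h + 2L, w + 2L)
  pad[2:(h + 1), 2:(w + 1)] <- mask
  core <- pad[2:(h + 1), 2:(w + 1)]
  exposed <- (core == 1L) * ((pad[1:h, 2:(w + 1)] == 0L) +
                             (pad[3:(h + 2), 2:(w + 1)] == 0L) +
                             (pad[2:(h + 1), 1:w] == 0L) +
                             (pad[2:(h + 1), 3:(w + 2)] == 0L))
  sum(exposed)
}

.polyArea <- function(pts) {
  x <- pts[, 1]; y <- pts[, 2]
  n <- nrow(pts)
  abs(sum(x * y[c(2:n, 1)] - x[c(2:n, 1)] * y)) / 2
}

## Pixelated convex area: the number of pixel centers lying inside (or on)
## the convex hull of the mask's pixel centers, as region-property toolkits
## compute it; a convex mask then has solidity exactly 1.
.convexArea <- function(mask) {
  b <- which(mask == 1, arr.ind = TRUE)
  hull <- grDevices::chull(b)
  hp <- b[hull, , drop = FALSE]
  if (nrow(hp) < 3L) return(nrow(b))
  rr <- range(b[, 1]); cr <- range(b[, 2])
  cand <- as.matrix(expand.grid(row = rr[1]:rr[2], col = cr[1]:cr[2]))
  # a point is inside a convex polygon iff every edge cross-product shares
  # the hull's orientation sign (with tolerance for on-edge points)
  n <- nrow(hp)
  nxt <- c(2:n, 1L)
  orient <- sum(hp[, 1] * hp[nxt, 2] - hp[nxt, 1] * hp[, 2])
  sgn <- if (orient >= 0) 1 else -1
  inside <- rep(TRUE, nrow(cand))
  for (i in seq_len(n)) {
    p1 <- hp[i, ]; p2 <- hp[nxt[i], ]
    cross <- (p2[1] - p1[1]) * (cand[, 2] - p1[2]) -
             (p2[2] - p1[2]) * (cand[, 1] - p1[1])
    inside <- inside & sgn * cross >= -1e-9
  }
  sum(inside)
}

#' Extract the 19 lesion descriptors from an image and ROI mask
#'
#' Geometry (area, perimeter, axis lengths, convexity, moment invariants)
#' comes from the binary mask; intensity statistics (mean, variance,
#' standard deviation) from the in-mask luminance; correlation, entropy and
#' energy from the in-mask grey-level co-occurrence matrix
#' ([computeGLCM()]).
#'
#' Definitions: `a`, `b` are the full major/minor axis lengths of the
#' intensity-equivalent ellipse (4 sqrt of the mask covariance
#' eigenvalues); `perimeter` is the Euclidean length of the traced outer
#' contour (the raw exposed-edge count is available with
#' `perimeterMethod = "edges"`); `irregularity_index = 4 pi area /
#' perimeter^2` (1 for a circle, smaller for irregular borders);
#' `compactness = perimeter^2 / (4 pi area)` (its reciprocal; the textbook
#' variant `2 N pi / area`, which is constant when area is the pixel count,
#' is available with `printedCompactness = TRUE`);
#' `eccentricity = sqrt(a^2 - b^2)/a`; `elongation_radius =
#' area / (2 maxRadius^2)` with maxRadius the largest centroid-to-boundary
#' distance; `elongation_axis = 2 area / (a pi)`; `rectangularity =
#' area/(a b)`; `form_factor = area / a^2`; `solidity = area / convex
#' area`; `hu_phi1..3` are the first three moment invariants of the mask.
#'
#' @param img image (RGB or grayscale, 0-255).
#' @param mask binary 0/1 matrix, at least 10 pixels.
#' @param levels GLCM grey levels.
#' @param perimeterMethod `"contour"` (Euclidean traced length, default) or
#'   `"edges"` (count of exposed pixel edges).
#' @param printedCompactness logical; use the constant textbook form.
#' @return named numeric vector of length 19 (see [featureNames()]).
#' @examples
#' s <- generateLesion(lesionSpec(), seed = 1)
#' round(extractFeatures(lesionImage(s), lesionMask(s)), 3)
#' @export
extractFeatures <- function(img, mask, levels = 8L,
                            perimeterMethod = c("contour", "edges"),
                            printedCompactness = FALSE) {
  perimeterMethod <- match.arg(perimeterMethod)
  mask <- (mask == 1) + 0L
  area <- sum(mask)
  if (area < 10) stop("mask must contain at least 10 pixels")
  gray <- .toGray(img)
  if (!all(dim(mask) == dim(gray))) stop("mask and image shapes differ")

  pix <- which(mask == 1, arr.ind = TRUE)
  cy <- mean(pix[, 1]); cx <- mean(pix[, 2])
  dy <- pix[, 1] - cy; dx <- pix[, 2] - cx
  mu20 <- mean(dx^2); mu02 <- mean(dy^2); mu11 <- mean(dx * dy)
  cov <- matrix(c(mu20, mu11, mu11, mu02), 2)
  ev <- eigen(cov, symmetric = TRUE)$values
  if (ev[2] < 1e-9) stop("degenerate mask (collinear pixels): eccentricity")
  aAxis <- 4 * sqrt(ev[1])   # full major axis
  bAxis <- 4 * sqrt(ev[2])

  exposed <- .exposedEdges(mask)
  boundary <- mask == 1 &
    (rbind(0L, mask[-nrow(mask), ]) == 0L |
     rbind(mask[-1, ], 0L) == 0L |
     cbind(0L, mask[, -ncol(mask)]) == 0L |
     cbind(mask[, -1], 0L) == 0L)
  bpix <- which(boundary, arr.ind = TRUE)
  maxRadius <- sqrt(max((bpix[, 1] - cy)^2 + (bpix[, 2] - cx)^2))
  perim <- if (perimeterMethod == "contour") .contourPerimeter(mask)
           else exposed
  if (!is.finite(perim) || perim <= 0)
    stop("degenerate mask (zero perimeter): perimeter")

  # Hu invariants from normalized central moments of the mask
  eta <- function(p, q) sum(dx^p * dy^q) / area^(1 + (p + q) / 2)
  e20 <- eta(2, 0); e02 <- eta(0, 2); e11 <- eta(1, 1)
  e30 <- eta(3, 0); e03 <- eta(0, 3); e21 <- eta(2, 1); e12 <- eta(1, 2)
  phi1 <- e20 + e02
  phi2 <- (e20 - e02)^2 + 4 * e11^2
  phi3 <- (e30 - 3 * e12)^2 + (3 * e21 - e03)^2

  inVals <- gray[mask == 1]
  g <- computeGLCM(img, mask, levels = levels)
  gs <- .glcmStats(g)

  compact <- if (printedCompactness) 2 * area * pi / area
             else perim^2 / (4 * pi * area)

  out <- c(
    elongation_radius = area / (2 * maxRadius^2),
    elongation_axis = 2 * area / (aAxis * pi),
    area = area,
    perimeter = perim,
    variance = mean((inVals - mean(inVals))^2),
    hu_phi1 = phi1, hu_phi2 = phi2, hu_phi3 = phi3,
    rectangularity = area / (aAxis * bAxis),
    irregularity_index = 4 * pi * area / perim^2,
    form_factor = area / aAxis^2,
    compactness = compact,
    mean = mean(inVals),
    correlation = gs$correlation,
    solidity = area / .convexArea(mask),
    entropy = gs$entropy,
    eccentricity = sqrt(aAxis^2 - bAxis^2) / aAxis,
    energy = gs$energy,
    standard_deviation = stats::sd(inVals) * sqrt((area - 1) / area)
  )
  out[featureNames()]
}
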