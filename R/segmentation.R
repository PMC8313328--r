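## Region-of-interest segmentation: SLIC superpixels -> per-superpixel
## quantized HSV histograms + Gabor texture energies -> kernel fuzzy C-means
## -> t-nearest-neighbour fuzzy-XOR affinity graph -> normalized spectral
## embedding -> k-means -> binary lesion mask.

#' Configuration for the segmentation chain
#'
#' @param nSuperpixels target number of SLIC superpixels.
#' @param compactness SLIC compactness (weight of the spatial term, in Lab
#'   units; larger gives more regular superpixels).
#' @param slicIterations SLIC update iterations.
#' @param kfcmC number of fuzzy clusters (2 = lesion vs background).
#' @param kernelRho Gaussian-kernel width; `NULL` uses the median pairwise
#'   squared distance of the feature table.
#' @param fuzzifier fuzzy exponent m (> 1).
#' @param tNeighbors nearest-neighbour count of the affinity graph.
#' @param spectralK number of spectral embedding dimensions / final clusters.
#' @param kmeansRestarts restarts of the final k-means.
#' @param lesionRule how the lesion cluster is identified: `"darker"` (lower
#'   mean luminance) or `"central"` (mean superpixel centroid closest to the
#'   image center).
#' @param seed seed for KFCM initialization and k-means.
#' @return a list of class `"segmentationConfig"`.
#' @export
segmentationConfig <- function(nSuperpixels = 400L, compactness = 10,
                               slicIterations = 10L, kfcmC = 2L,
                               kernelRho = NULL, fuzzifier = 2,
                               tNeighbors = 10L, spectralK = 2L,
                               kmeansRestarts = 10L,
                               lesionRule = c("darker", "central"),
                               seed = 1L) {
  if (kfcmC < 2L) stop("kfcmC must be >= 2")
  if (fuzzifier <= 1) stop("fuzzifier must be > 1")
  structure(list(
    nSuperpixels = as.integer(nSuperpixels), compactness = compactness,
    slicIterations = as.integer(slicIterations), kfcmC = as.integer(kfcmC),
    kernelRho = kernelRho, fuzzifier = fuzzifier,
    tNeighbors = as.integer(tNeighbors), spectralK = as.integer(spectralK),
    kmeansRestarts = as.integer(kmeansRestarts),
    lesionRule = match.arg(lesionRule), seed = as.integer(seed)
  ), class = "segmentationConfig")
}

.toGray <- function(img) {
  if (length(dim(img)) == 2L) return(img)
  0.299 * img[, , 1] + 0.587 * img[, , 2] + 0.114 * img[, , 3]
}

.toLab <- function(img) {
  d <- dim(img)
  rgb <- cbind(as.vector(img[, , 1]), as.vector(img[, , 2]),
               as.vector(img[, , 3])) / 255
  grDevices::convertColor(rgb, from = "sRGB", to = "Lab")
}

## Minimum-label propagation: connected components of a label image
## (4-connectivity) by alternating raster sweeps.
.connectedComponents <- function(labels) {
  h <- nrow(labels); w <- ncol(labels)
  comp <- matrix(seq_len(h * w), h, w)
  repeat {
    old <- comp
    up <- rbind(comp[1, , drop = FALSE], comp[-h, , drop = FALSE])
    same <- rbind(rep(FALSE, w), labels[-1, , drop = FALSE] ==
                    labels[-h, , drop = FALSE])
    comp[same] <- pmin(comp[same], up[same])
    dn <- rbind(comp[-1, , drop = FALSE], comp[h, , drop = FALSE])
    same <- rbind(labels[-h, , drop = FALSE] == labels[-1, , drop = FALSE],
                  rep(FALSE, w))
    comp[same] <- pmin(comp[same], dn[same])
    lf <- cbind(comp[, 1, drop = FALSE], comp[, -w, drop = FALSE])
    same <- cbind(rep(FALSE, h), labels[, -1, drop = FALSE] ==
                    labels[, -w, drop = FALSE])
    comp[same] <- pmin(comp[same], lf[same])
    rt <- cbind(comp[, -1, drop = FALSE], comp[, w, drop = FALSE])
    same <- cbind(labels[, -w, drop = FALSE] == labels[, -1, drop = FALSE],
                  rep(FALSE, h))
    comp[same] <- pmin(comp[same], rt[same])
    if (identical(comp, old)) break
  }
  matrix(match(comp, sort(unique(as.vector(comp)))), h, w)
}

#' SLIC superpixel over-segmentation
#'
#' Localized k-means in (L, a, b, row, col) space: cluster centers start on
#' a regular grid with spacing `S = sqrt(npixels / nSuperpixels)`, each
#' center competes only for pixels within a 2S window, and the distance is
#' `sqrt(dLab^2 + (dxy / S)^2 * compactness^2)`. Connectivity is enforced
#' afterwards by reassigning stray fragments to an adjacent superpixel.
#'
#' @param img RGB image (H x W x 3, 0-255).
#' @param nSuperpixels target superpixel count.
#' @param compactness spatial-term weight.
#' @param iterations update iterations.
#' @return integer H x W matrix of labels `1..K` (every label non-empty and
#'   spatially connected), with `K` as attribute `"K"`.
#' @export
slicSuperpixels <- function(img, nSuperpixels = 400L, compactness = 10,
                            iterations = 10L) {
  d <- dim(img)
  if (length(d) != 3L) stop("slicSuperpixels expects an RGB image")
  h <- d[1]; w <- d[2]
  npix <- h * w
  if (nSuperpixels >= npix) stop("more superpixels than pixels")
  lab <- .toLab(img)
  S <- sqrt(npix / nSuperpixels)
  rc <- seq(S / 2, h, by = S)
  cc <- seq(S / 2, w, by = S)
  centers <- as.matrix(expand.grid(row = rc, col = cc))
  K <- nrow(centers)
  cLab <- lab[(round(centers[, "col"]) - 1) * h + round(centers[, "row"]), ,
              drop = FALSE]
  rowIdx <- rep(seq_len(h), w)
  colIdx <- rep(seq_len(w), each = h)
  assign <- integer(npix)
  bestD <- rep(Inf, npix)
  m2 <- compactness^2
  for (it in seq_len(iterations)) {
    bestD[] <- Inf
    for (k in seq_len(K)) {
      r0 <- max(1L, floor(centers[k, 1] - 2 * S))
      r1 <- min(h, ceiling(centers[k, 1] + 2 * S))
      c0 <- max(1L, floor(centers[k, 2] - 2 * S))
      c1 <- min(w, ceiling(centers[k, 2] + 2 * S))
      rr <- r0:r1; ccc <- c0:c1
      idx <- as.vector(outer(rr, (ccc - 1L) * h, "+"))
      dLab <- (lab[idx, 1] - cLab[k, 1])^2 + (lab[idx, 2] - cLab[k, 2])^2 +
        (lab[idx, 3] - cLab[k, 3])^2
      dxy <- (rowIdx[idx] - centers[k, 1])^2 + (colIdx[idx] - centers[k, 2])^2
      dist <- dLab + dxy / S^2 * m2
      better <- dist < bestD[idx]
      ib <- idx[better]
      bestD[ib] <- dist[better]
      assign[ib] <- k
    }
    # update centers
    for (k in seq_len(K)) {
      members <- assign == k
      if (!any(members)) next
      centers[k, 1] <- mean(rowIdx[members])
      centers[k, 2] <- mean(colIdx[members])
      cLab[k, ] <- colMeans(lab[members, , drop = FALSE])
    }
  }
  labels <- matrix(assign, h, w)
  # enforce connectivity: keep the largest fragment of each label, merge
  # the rest into the dominant adjacent superpixel
  comp <- .connectedComponents(labels)
  tab <- table(comp, labels)
  keep <- integer(0)
  for (k in sort(unique(assign))) {
    col <- tab[, as.character(k)]
    keep <- c(keep, as.integer(rownames(tab)[which.max(col)]))
  }
  stray <- !(comp %in% keep)
  while (any(stray)) {
    strayComps <- unique(comp[stray])
    changed <- FALSE
    for (sc in strayComps) {
      pix <- which(comp == sc)
      rr <- ((pix - 1L) %% h) + 1L
      ccx <- ((pix - 1L) %/% h) + 1L
      nb <- rbind(cbind(rr - 1L, ccx), cbind(rr + 1L, ccx),
                  cbind(rr, ccx - 1L), cbind(rr, ccx + 1L))
      ok <- nb[, 1] >= 1L & nb[, 1] <= h & nb[, 2] >= 1L & nb[, 2] <= w
      nb <- nb[ok, , drop = FALSE]
      nbi <- (nb[, 2] - 1L) * h + nb[, 1]
      good <- comp[nbi] %in% keep
      if (!any(good)) next
      lbl <- labels[nbi[good]]
      newLabel <- as.integer(names(which.max(table(lbl))))
      labels[pix] <- newLabel
      comp[pix] <- keep[match(newLabel, sort(unique(assign)))]
      changed <- TRUE
    }
    stray <- !(comp %in% keep)
    if (!changed) break
  }
  # compact label ids to 1..K
  labels <- matrix(match(labels, sort(unique(as.vector(labels)))), h, w)
  attr(labels, "K") <- max(labels)
  labels
}

#' Quantized HSV color histograms per superpixel
#'
#' Hue is quantized to 8 bins, saturation to 4, value to 2; each
#' sub-histogram is normalized to sum to 1, giving 14 color descriptors per
#' superpixel.
#'
#' @param img RGB image.
#' @param labels superpixel label matrix from [slicSuperpixels()].
#' @return K x 14 matrix (columns `h1..h8, s1..s4, v1..v2`).
#' @export
colorFeatures <- function(img, labels) {
  K <- max(labels)
  hsv <- grDevices::rgb2hsv(as.vector(img[, , 1]), as.vector(img[, , 2]),
                            as.vector(img[, , 3]), maxColorValue = 255)
  bins <- function(x, n) pmin(floor(x * n), n - 1L) + 1L
  hb <- bins(hsv[1, ], 8L); sb <- bins(hsv[2, ], 4L); vb <- bins(hsv[3, ], 2L)
  lab <- as.vector(labels)
  out <- matrix(0, K, 14L,
                dimnames = list(NULL, c(paste0("h", 1:8), paste0("s", 1:4),
                                        paste0("v", 1:2))))
  hTab <- table(factor(lab, 1:K), factor(hb, 1:8))
  sTab <- table(factor(lab, 1:K), factor(sb, 1:4))
  vTab <- table(factor(lab, 1:K), factor(vb, 1:2))
  out[, 1:8] <- hTab / rowSums(hTab)
  out[, 9:12] <- sTab / rowSums(sTab)
  out[, 13:14] <- vTab / rowSums(vTab)
  out
}

.gaborKernel <- function(wavelength, theta, sigma = 0.56 * wavelength,
                         gammaAspect = 0.5) {
  r <- ceiling(3 * sigma)
  gx <- matrix(rep(-r:r, each = 2 * r + 1), 2 * r + 1)
  gy <- matrix(rep(-r:r, times = 2 * r + 1), 2 * r + 1)
  xp <- gx * cos(theta) + gy * sin(theta)
  yp <- -gx * sin(theta) + gy * cos(theta)
  k <- exp(-(xp^2 + gammaAspect^2 * yp^2) / (2 * sigma^2)) *
    cos(2 * pi * xp / wavelength)
  k - mean(k)   # zero-mean: no DC response
}

#' Multiscale directional texture energies per superpixel
#'
#' Default backend is a Gabor filter bank (2 wavelengths x 4 orientations,
#' zero-mean kernels); per superpixel the mean absolute filter response
#' (energy) is recorded. The backend is pluggable: supply a list of kernel
#' matrices via `kernels` to use a different multiscale directional
#' decomposition.
#'
#' @param img image (RGB or grayscale); converted to luminance.
#' @param labels superpixel label matrix.
#' @param backend `"gabor"` (default) or `"custom"` (requires `kernels`).
#' @param wavelengths,orientations Gabor bank parameters (orientations in
#'   radians; the orientation is the direction of intensity variation).
#' @param kernels list of convolution kernels for the custom backend.
#' @return K x T matrix of non-negative energies (T = number of filters).
#' @export
textureFeatures <- function(img, labels, backend = c("gabor", "custom"),
                            wavelengths = c(4, 8),
                            orientations = pi * (0:3) / 4,
                            kernels = NULL) {
  backend <- match.arg(backend)
  gray <- .toGray(img) / 255
  if (backend == "gabor") {
    kernels <- list()
    nmv <- character(0)
    for (wl in wavelengths) for (th in orientations) {
      kernels[[length(kernels) + 1L]] <- .gaborKernel(wl, th)
      nmv <- c(nmv, sprintf("gabor_w%g_o%d", wl, round(th * 180 / pi)))
    }
  } else {
    if (is.null(kernels)) stop("custom backend requires kernels")
    nmv <- paste0("tex", seq_along(kernels))
  }
  K <- max(labels)
  lab <- factor(as.vector(labels), 1:K)
  out <- matrix(0, K, length(kernels), dimnames = list(NULL, nmv))
  for (j in seq_along(kernels)) {
    resp <- abs(as.matrix(EBImage::filter2(EBImage::Image(gray),
                                           kernels[[j]])))
    out[, j] <- tapply(as.vector(resp), lab, mean)
  }
  out
}

#' Kernel fuzzy C-means clustering
#'
#' Fuzzy clustering with distances measured through a Gaussian kernel
#' `K(x, v) = exp(-||x - v||^2 / rho)`. Memberships and centers alternate:
#' `u_ik` proportional to `(1 - K(x_k, v_i))^(-1/(m-1))` normalized per
#' sample, and `v_i = sum_k u_ik^m K(x_k, v_i) x_k / sum_k u_ik^m K(x_k,
#' v_i)`. Stops when the largest membership change falls below `tol`.
#'
#' @param x n x p data matrix (rows are samples).
#' @param c number of clusters.
#' @param rho kernel width; `NULL` uses the median pairwise squared distance.
#' @param m fuzzifier (> 1).
#' @param maxIter,tol stopping rule.
#' @param seed seed for the initial centers (c distinct samples).
#' @return list with `u` (c x n memberships, columns sum to 1), `centers`
#'   (c x p), `objective` (per-iteration trace of `2 * sum u^m (1 - K)`),
#'   `rho` and `iterations`.
#' @export
kernelFuzzyCMeans <- function(x, c = 2L, rho = NULL, m = 2, maxIter = 300L,
                              tol = 1e-5, seed = 1L) {
  x <- as.matrix(x)
  n <- nrow(x)
  if (c > n) stop("more clusters than samples")
  if (is.null(rho)) {
    idx <- if (n > 400L) sample.int(n, 400L) else seq_len(n)
    d2 <- as.vector(stats::dist(x[idx, , drop = FALSE]))^2
    rho <- stats::median(d2)
    if (!is.finite(rho) || rho <= 0) rho <- 1
  }
  set.seed(seed)
  centers <- x[sample.int(n, c), , drop = FALSE]
  uPrev <- matrix(1 / c, c, n)
  obj <- numeric(0)
  kernelTo <- function(v) {
    d2 <- outer(rowSums(v^2), rowSums(x^2), "+") - 2 * tcrossprod(v, x)
    exp(-pmax(d2, 0) / rho)
  }
  for (it in seq_len(maxIter)) {
    Km <- kernelTo(centers)                       # c x n
    dis <- pmax(1 - Km, 1e-12)
    u <- dis^(-1 / (m - 1))
    u <- sweep(u, 2L, colSums(u), "/")
    obj <- c(obj, 2 * sum(u^m * dis))
    wm <- u^m * Km
    centers <- sweep(wm %*% x, 1L, rowSums(wm), "/")
    if (max(abs(u - uPrev)) < tol) { uPrev <- u; break }
    uPrev <- u
  }
  list(u = uPrev, centers = centers, objective = obj, rho = rho,
       iterations = length(obj))
}

.fuzzyXor <- function(u) {
  # u: c x n memberships; returns n x n mean-over-clusters fuzzy XOR
  n <- ncol(u)
  acc <- matrix(0, n, n)
  for (ci in seq_len(nrow(u))) {
    a <- u[ci, ]
    acc <- acc + pmax(outer(a, 1 - a, pmin), outer(1 - a, a, pmin))
  }
  acc / nrow(u)
}

#' Build the t-nearest-neighbour fuzzy-XOR affinity graph
#'
#' Pairs that are not mutual-or-one-way t-nearest neighbours in feature
#' space get affinity 0; neighbouring pairs whose hardened memberships agree
#' get 1; all other neighbouring pairs get `exp(-ln(2) * xor(u_i, u_j))`
#' where the fuzzy XOR is the mean over clusters of
#' `max(min(a, 1-b), min(1-a, b))` (0 for identical crisp memberships, so
#' the formula branch is consistent with the same-cluster branch). The
#' increasing variant `exp(+ln(2) * xor)` is available with
#' `flipSign = FALSE`.
#'
#' @param u c x n membership matrix from [kernelFuzzyCMeans()].
#' @param features n x p feature matrix used for the neighbour search.
#' @param tNeighbors neighbourhood size t (< n).
#' @param flipSign logical; use the decreasing (similarity) form.
#' @return list with `W` (n x n symmetric affinity), `D` (degree vector,
#'   row sums of W) and `t`.
#' @export
buildAffinity <- function(u, features, tNeighbors = 10L, flipSign = TRUE) {
  n <- ncol(u)
  if (tNeighbors >= n) stop("tNeighbors must be smaller than the sample count")
  dm <- as.matrix(stats::dist(features))
  diag(dm) <- Inf
  nn <- t(apply(dm, 1L, function(r) rank(r, ties.method = "first") <=
                  tNeighbors))
  adj <- nn | t(nn)
  hard <- apply(u, 2L, which.max)
  xorM <- .fuzzyXor(u)
  sgn <- if (flipSign) -1 else 1
  W <- exp(sgn * log(2) * xorM)
  same <- outer(hard, hard, "==")
  W[same] <- 1
  W[!adj] <- 0
  diag(W) <- 1
  W <- (W + t(W)) / 2
  list(W = W, D = rowSums(W), t = tNeighbors)
}

#' Normalized spectral embedding of an affinity graph
#'
#' Forms the symmetrically normalized matrix `D^(-1/2) W D^(-1/2)`, takes
#' the eigenvectors of the `k` largest eigenvalues and normalizes each row
#' of the resulting n x k matrix to unit length.
#'
#' @param graph list with `W` (and optionally `D`) as returned by
#'   [buildAffinity()], or a plain affinity matrix.
#' @param k embedding dimension.
#' @return n x k matrix `Y` with unit-norm rows; eigenvalues in
#'   `attr(, "values")`.
#' @export
spectralEmbed <- function(graph, k = 2L) {
  W <- if (is.list(graph)) graph$W else graph
  n <- nrow(W)
  if (k > n) stop("k must not exceed the node count")
  deg <- rowSums(W)
  dinv <- 1 / sqrt(deg + 1e-12)
  L <- W * tcrossprod(dinv)
  eig <- eigen(L, symmetric = TRUE)
  Y <- eig$vectors[, seq_len(k), drop = FALSE]
  nrm <- sqrt(rowSums(Y^2))
  Y <- Y / pmax(nrm, 1e-12)
  attr(Y, "values") <- eig$values
  Y
}

#' Segment the lesion region of an image
#'
#' Runs the full chain: SLIC superpixels, HSV + Gabor features, kernel
#' fuzzy C-means, fuzzy-XOR affinity, spectral embedding and k-means, then
#' paints the binary mask of the lesion cluster. With `lesionRule =
#' "darker"` the cluster whose member superpixels have the lower mean
#' luminance is the lesion (ties broken toward the cluster closer to the
#' image center); `"central"` picks the spatially central cluster directly.
#'
#' @param img preprocessed RGB image (0-255).
#' @param config a [segmentationConfig()].
#' @param details logical; also return the intermediate stages.
#' @return the binary H x W mask (0/1 integer matrix), or (with
#'   `details = TRUE`) a list with `mask`, `labels`, `features`, `kfcm`,
#'   `graph`, `embedding` and `clusters`.
#' @export
segmentLesion <- function(img, config = segmentationConfig(),
                          details = FALSE) {
  stopifnot(inherits(config, "segmentationConfig"))
  labels <- slicSuperpixels(img, config$nSuperpixels, config$compactness,
                            config$slicIterations)
  K <- attr(labels, "K")
  tex <- textureFeatures(img, labels)
  texScale <- max(abs(tex))
  if (texScale > 0) tex <- tex / texScale   # texture block on the histogram scale
  feats <- cbind(colorFeatures(img, labels), tex)
  kf <- kernelFuzzyCMeans(feats, c = config$kfcmC, rho = config$kernelRho,
                          m = config$fuzzifier, seed = config$seed)
  tN <- min(config$tNeighbors, K - 1L)
  graph <- buildAffinity(kf$u, feats, tN)
  Y <- spectralEmbed(graph, config$spectralK)
  set.seed(config$seed + 1L)
  km <- stats::kmeans(Y, centers = config$spectralK,
                      nstart = config$kmeansRestarts)
  cl <- km$cluster

  gray <- .toGray(img)
  lumin <- tapply(as.vector(gray), factor(as.vector(labels), 1:K), mean)
  h <- nrow(gray); w <- ncol(gray)
  rowIdx <- rep(seq_len(h), w); colIdx <- rep(seq_len(w), each = h)
  labVec <- as.vector(labels)
  cRow <- tapply(rowIdx, factor(labVec, 1:K), mean)
  cCol <- tapply(colIdx, factor(labVec, 1:K), mean)
  centerDist <- vapply(seq_len(config$spectralK), function(g) {
    mean(sqrt((cRow[cl == g] - (h + 1) / 2)^2 +
              (cCol[cl == g] - (w + 1) / 2)^2))
  }, numeric(1))
  meanLum <- vapply(seq_len(config$spectralK),
                    function(g) mean(lumin[cl == g]), numeric(1))
  lesionCluster <- if (config$lesionRule == "darker") {
    cand <- which(abs(meanLum - min(meanLum)) < 1e-9)
    if (length(cand) > 1L) cand[which.min(centerDist[cand])] else cand
  } else which.min(centerDist)

  mask <- matrix(0L, h, w)
  mask[labVec %in% which(cl == lesionCluster)] <- 1L
  if (!details) return(mask)
  list(mask = mask, labels = labels, features = feats, kfcm = kf,
       graph = graph, embedding = Y, clusters = cl)
}

#' Dice overlap coefficient between two binary masks
#'
#' `2|A n B| / (|A| + |B|)`; 1 for identical non-empty masks.
#'
#' @param a,b binary masks of the same shape.
#' @return the Dice coefficient in `[0, 1]`.
#' @export
diceCoefficient <- function(a, b) {
  if (!all(dim(a) == dim(b))) stop("mask shapes differ")
  sa <- sum(a == 1); sb <- sum(b == 1)
  if (sa + sb == 0) return(1)
  2 * sum(a == 1 & b == 1) / (sa + sb)
}
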