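## Seeded generators for dermoscopy-like test data: lesion images with exact
## ground-truth masks, and labelled 19-column feature tables with a
## controlled number of informative columns.

#' Specification of a synthetic lesion image
#'
#' The lesion boundary is a radially perturbed ellipse:
#' `r(theta) = rEllipse(theta) * (1 + sum_h A_h cos(h*theta + phi_h))`,
#' with harmonics `h = 2, ..., 1 + nHarmonics` and equal amplitudes
#' `A_h = irregularity / sqrt(nHarmonics)` (so the enclosed area is
#' analytically `pi*a*b*(1 + irregularity^2/2)` to first order). Phases are
#' drawn at generation time. A sample is labelled `"malignant"` when the
#' boundary is strongly irregular and the ellipse strongly asymmetric
#' (`irregularity >= 0.12` and `a/b >= 1.3`), mimicking the border-
#' irregularity and asymmetry cues used clinically.
#'
#' @param size image height and width in pixels.
#' @param center lesion center (row, col); defaults to the image center.
#' @param a,b ellipse semi-axes in pixels.
#' @param irregularity total relative amplitude of the radial boundary
#'   perturbation (root-sum-square over harmonics); must be < 0.5.
#' @param nHarmonics number of Fourier harmonics perturbing the boundary.
#' @param rotation ellipse rotation in radians.
#' @param lesionColor,skinColor RGB triplets (0-255) for lesion and skin.
#' @param textureSigma per-pixel Gaussian texture inside each region.
#' @param noiseSigma Gaussian sensor noise added to the whole image.
#' @param saltPepperDensity impulse-noise density applied last.
#' @param hairCount number of dark hair strokes (0 disables).
#' @return a validated list of class `"lesionSpec"`.
#' @export
lesionSpec <- function(size = c(128L, 128L), center = NULL, a = 28, b = 22,
                       irregularity = 0.05, nHarmonics = 4L, rotation = 0,
                       lesionColor = c(95, 65, 50),
                       skinColor = c(205, 170, 150),
                       textureSigma = 6, noiseSigma = 5,
                       saltPepperDensity = 0.02, hairCount = 0L) {
  size <- rep_len(as.integer(size), 2L)
  if (is.null(center)) center <- (size + 1) / 2
  if (a < b) { tmp <- a; a <- b; b <- tmp }
  if (irregularity < 0 || irregularity >= 0.5)
    stop("irregularity must lie in [0, 0.5)")
  maxR <- a * (1 + irregularity)
  if (center[1] - maxR < 1 || center[1] + maxR > size[1] ||
      center[2] - maxR < 1 || center[2] + maxR > size[2])
    stop("lesion must fit fully inside the canvas")
  structure(list(
    size = size, center = center, a = a, b = b,
    irregularity = irregularity, nHarmonics = as.integer(nHarmonics),
    rotation = rotation, lesionColor = lesionColor, skinColor = skinColor,
    textureSigma = textureSigma, noiseSigma = noiseSigma,
    saltPepperDensity = saltPepperDensity, hairCount = as.integer(hairCount)
  ), class = "lesionSpec")
}

.lesionLabelRule <- function(spec) {
  if (spec$irregularity >= 0.12 && spec$a / spec$b >= 1.3) "malignant"
  else "benign"
}

.drawHair <- function(channelList, spec) {
  h <- spec$size[1]; w <- spec$size[2]
  for (k in seq_len(spec$hairCount)) {
    p0 <- c(stats::runif(1, 1, h), stats::runif(1, 1, w))
    p2 <- c(stats::runif(1, 1, h), stats::runif(1, 1, w))
    p1 <- (p0 + p2) / 2 + stats::rnorm(2, 0, h / 4)
    tt <- seq(0, 1, length.out = 4L * max(h, w))
    pts <- outer((1 - tt)^2, p0) + outer(2 * tt * (1 - tt), p1) +
      outer(tt^2, p2)
    ri <- pmin(pmax(round(pts[, 1]), 1L), h)
    ci <- pmin(pmax(round(pts[, 2]), 1L), w)
    shade <- stats::runif(1, 20, 60)
    for (ch in 1:3) {
      m <- channelList[[ch]]
      m[cbind(ri, ci)] <- shade
      channelList[[ch]] <- m
    }
  }
  channelList
}

#' Generate a synthetic dermoscopy-like lesion sample
#'
#' Renders the lesion described by `spec` on a skin-coloured background,
#' adds region texture, optional hair strokes, Gaussian noise and
#' salt-and-pepper impulses (in that order), and returns it together with
#' the exact ground-truth mask of the generating boundary.
#'
#' @param spec a [lesionSpec()].
#' @param seed integer seed; the sample is a pure function of (spec, seed).
#' @return a [LesionSample-class] object.
#' @examples
#' s <- generateLesion(lesionSpec(), seed = 1)
#' s
#' @export
generateLesion <- function(spec, seed = 1L) {
  stopifnot(inherits(spec, "lesionSpec"))
  set.seed(seed)
  h <- spec$size[1]; w <- spec$size[2]
  nH <- spec$nHarmonics
  harmonics <- seq(2L, length.out = nH)
  amp <- rep(spec$irregularity / sqrt(nH), nH)
  phi <- stats::runif(nH, 0, 2 * pi)

  row <- matrix(seq_len(h), h, w)
  col <- matrix(seq_len(w), h, w, byrow = TRUE)
  dy <- row - spec$center[1]
  dx <- col - spec$center[2]
  theta <- atan2(dy, dx)
  rho <- sqrt(dx^2 + dy^2)
  thetaE <- theta - spec$rotation
  rEll <- spec$a * spec$b /
    sqrt((spec$b * cos(thetaE))^2 + (spec$a * sin(thetaE))^2)
  pert <- 0
  for (k in seq_len(nH))
    pert <- pert + amp[k] * cos(harmonics[k] * theta + phi[k])
  mask <- (rho <= rEll * (1 + pert)) + 0L
  dim(mask) <- c(h, w)

  chans <- vector("list", 3L)
  for (ch in 1:3) {
    skin <- spec$skinColor[ch] + stats::rnorm(h * w, 0, spec$textureSigma)
    les <- spec$lesionColor[ch] + stats::rnorm(h * w, 0, spec$textureSigma)
    chans[[ch]] <- matrix(ifelse(mask == 1L, les, skin), h, w)
  }
  if (spec$hairCount > 0L) chans <- .drawHair(chans, spec)
  img <- array(0, dim = c(h, w, 3L))
  for (ch in 1:3) {
    m <- chans[[ch]] + stats::rnorm(h * w, 0, spec$noiseSigma)
    img[, , ch] <- pmin(pmax(.roundHalfUp(m), 0), 255)
  }
  if (spec$saltPepperDensity > 0)
    img <- addSaltPepper(img, spec$saltPepperDensity)
  new("LesionSample", image = img, mask = mask,
      label = .lesionLabelRule(spec), spec = unclass(spec))
}

#' Draw a random lesion specification for one class
#'
#' Benign lesions get mild boundary irregularity (0.02-0.08) and near-round
#' axes (ratio 1.0-1.25); malignant lesions get strong irregularity
#' (0.14-0.22) and elongated axes (ratio 1.35-1.7). Draws from the current
#' RNG stream.
#'
#' @param label `"benign"` or `"malignant"`.
#' @param size image size.
#' @param ... further arguments passed to [lesionSpec()].
#' @return a [lesionSpec()].
#' @export
randomLesionSpec <- function(label = c("benign", "malignant"),
                             size = c(128L, 128L), ...) {
  label <- match.arg(label)
  scale <- min(size) / 128
  if (label == "benign") {
    irr <- stats::runif(1, 0.02, 0.08)
    ratio <- stats::runif(1, 1.0, 1.25)
  } else {
    irr <- stats::runif(1, 0.14, 0.22)
    ratio <- stats::runif(1, 1.35, 1.7)
  }
  a <- stats::runif(1, 24, 30) * scale
  jitterC <- stats::runif(2, -6, 6) * scale
  lesionJitter <- round(stats::runif(3, -15, 15))
  lesionSpec(size = size, center = (size + 1) / 2 + jitterC,
             a = a, b = a / ratio, irregularity = irr,
             rotation = stats::runif(1, 0, pi),
             lesionColor = pmax(c(95, 65, 50) + lesionJitter, 20), ...)
}

#' Generate a battery of labelled lesion samples
#'
#' Alternates benign and malignant specifications, each rendered with its
#' own derived seed, so a battery is reproducible from a single seed.
#'
#' @param n number of samples.
#' @param seed base seed.
#' @param size image size.
#' @param ... passed to [randomLesionSpec()].
#' @return list of [LesionSample-class] objects.
#' @export
generateLesionBattery <- function(n, seed = 1L, size = c(128L, 128L), ...) {
  lapply(seq_len(n), function(i) {
    set.seed(seed + 1000L * i)
    spec <- randomLesionSpec(if (i %% 2L == 0L) "malignant" else "benign",
                             size = size, ...)
    generateLesion(spec, seed = seed + 1000L * i + 1L)
  })
}

#' Generate a labelled 19-feature table with planted signal
#'
#' Columns are named after the lesion descriptors ([featureNames()]).
#' `nInformative` randomly chosen columns are drawn from class-shifted
#' Gaussians (shift `effectSize` standard deviations between classes); all
#' other columns are pure N(0, 1) noise. Labels are balanced.
#'
#' @param nSamples number of rows (split evenly between classes).
#' @param nInformative number of informative columns (0-19).
#' @param effectSize class shift in units of the feature's SD.
#' @param seed integer seed.
#' @return list with `features` (data.frame), `labels` (factor
#'   benign/malignant) and `informative` (column indices carrying signal).
#' @export
generateFeatureTable <- function(nSamples = 200L, nInformative = 2L,
                                 effectSize = 2, seed = 1L) {
  nm <- featureNames()
  if (nInformative > length(nm)) stop("at most ", length(nm),
                                      " informative features")
  set.seed(seed)
  n1 <- nSamples %/% 2L
  labels <- factor(rep(c("benign", "malignant"), c(nSamples - n1, n1)),
                   levels = c("benign", "malignant"))
  informative <- sort(sample.int(length(nm), nInformative))
  X <- matrix(stats::rnorm(nSamples * length(nm)), nSamples, length(nm))
  shift <- ifelse(labels == "malignant", effectSize / 2, -effectSize / 2)
  for (j in informative) X[, j] <- X[, j] + shift
  colnames(X) <- nm
  list(features = as.data.frame(X), labels = labels,
       informative = informative)
}
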