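## Image preprocessing: median-filter noise reduction and global lookup-table
## contrast stretching. Images are plain arrays of 8-bit intensities:
## a height x width matrix (grayscale) or height x width x 3 array (RGB),
## values 0-255.

.assertImage <- function(img) {
  d <- dim(img)
  if (is.null(d) || !(length(d) == 2L || (length(d) == 3L && d[3] == 3L)))
    stop("image must be a H x W matrix or H x W x 3 array")
  if (d[1] < 3L || d[2] < 3L) stop("image must be at least 3 x 3")
  if (min(img) < 0 || max(img) > 255) stop("image values must lie in [0, 255]")
  invisible(d)
}

.roundHalfUp <- function(x) floor(x + 0.5)

.padReplicate <- function(m, r) {
  ri <- c(rep(1L, r), seq_len(nrow(m)), rep(nrow(m), r))
  ci <- c(rep(1L, r), seq_len(ncol(m)), rep(ncol(m), r))
  m[ri, ci]
}

.medianFilterChannel <- function(m, r) {
  p <- .padReplicate(m, r)
  f <- EBImage::imageData(EBImage::medianFilter(EBImage::Image(p / 255), r))
  .roundHalfUp(f * 255)[(r + 1):(r + nrow(m)), (r + 1):(r + ncol(m))]
}

#' Median-filter an 8-bit image
#'
#' Each pixel is replaced by the median of its `window` x `window`
#' neighborhood, per channel; image borders are handled by edge replication.
#' Median filtering removes salt-and-pepper impulses while preserving edges.
#'
#' @param img 8-bit image (matrix or H x W x 3 array).
#' @param window odd window size, >= 3 (default 3, i.e. a 3 x 3 mask).
#' @return filtered image of the same shape, integer values in `[0, 255]`.
#' @examples
#' img <- matrix(0, 9, 9); img[5, 5] <- 255
#' max(medianFilterImage(img))  # 0: the impulse is removed
#' @export
medianFilterImage <- function(img, window = 3L) {
  d <- .assertImage(img)
  window <- as.integer(window)
  if (window %% 2L == 0L || window < 3L)
    stop("window must be an odd integer >= 3")
  r <- window %/% 2L
  if (length(d) == 2L) return(.medianFilterChannel(img, r))
  out <- img
  for (ch in 1:3) out[, , ch] <- .medianFilterChannel(img[, , ch], r)
  out
}

.stretchLUT <- function(lo, hi) {
  if (hi <= lo) stop("degenerate input: image has no intensity range to stretch")
  v <- 0:255
  lut <- .roundHalfUp(255 * (pmin(pmax(v, lo), hi) - lo) / (hi - lo))
  lut
}

#' Global contrast stretching through an 8-bit lookup table
#'
#' Linearly maps the observed minimum and maximum intensity to 0 and 255 via
#' a 256-entry lookup table (round-half-up). For RGB images the default
#' `"value"` mode stretches the V channel of HSV (rescaling R, G, B by a
#' common factor per pixel) so hue and saturation are untouched; mode
#' `"perchannel"` stretches each channel independently.
#'
#' @param img 8-bit image.
#' @param mode for RGB input, `"value"` (default) or `"perchannel"`.
#' @return contrast-stretched image, same shape, values in `[0, 255]` with
#'   observed min/max mapped to 0/255.
#' @examples
#' m <- matrix(c(50, 125, 200), 3, 3)
#' unique(as.vector(stretchContrast(m)))  # 0, 128, 255
#' @export
stretchContrast <- function(img, mode = c("value", "perchannel")) {
  d <- .assertImage(img)
  mode <- match.arg(mode)
  if (length(d) == 2L) {
    lut <- .stretchLUT(min(img), max(img))
    return(matrix(lut[img + 1L], d[1], d[2]))
  }
  if (mode == "perchannel") {
    out <- img
    for (ch in 1:3) {
      lut <- .stretchLUT(min(img[, , ch]), max(img[, , ch]))
      out[, , ch] <- lut[img[, , ch] + 1L]
    }
    return(out)
  }
  v <- pmax(img[, , 1], pmax(img[, , 2], img[, , 3]))
  lut <- .stretchLUT(min(v), max(v))
  vNew <- matrix(lut[v + 1L], d[1], d[2])
  scale <- ifelse(v > 0, vNew / v, 0)
  out <- img
  for (ch in 1:3) {
    out[, , ch] <- pmin(.roundHalfUp(img[, , ch] * scale), 255)
  }
  # black pixels get the stretched value directly (gray, hue undefined)
  black <- v == 0
  if (any(black)) for (ch in 1:3) {
    o <- out[, , ch]; o[black] <- vNew[black]; out[, , ch] <- o
  }
  out
}

#' Corrupt an image with salt-and-pepper noise
#'
#' Each pixel is independently corrupted with probability `density`, set to 0
#' or 255 with equal probability (all channels together for RGB).
#'
#' @param img 8-bit image.
#' @param density corruption probability per pixel, in `[0, 1]`.
#' @param seed optional integer; when supplied the corruption pattern is
#'   reproducible.
#' @return corrupted image of the same shape.
#' @export
addSaltPepper <- function(img, density, seed = NULL) {
  d <- .assertImage(img)
  if (density < 0 || density > 1) stop("density must lie in [0, 1]")
  if (!is.null(seed)) set.seed(seed)
  npix <- d[1] * d[2]
  hit <- stats::runif(npix) < density
  val <- ifelse(stats::runif(npix) < 0.5, 0, 255)
  if (length(d) == 2L) {
    img[hit] <- val[hit]
  } else {
    for (ch in 1:3) {
      o <- img[, , ch]; o[hit] <- val[hit]; img[, , ch] <- o
    }
  }
  img
}

#' Peak signal-to-noise ratio between two 8-bit images
#'
#' @param reference,image same-shaped 8-bit images.
#' @return PSNR in dB (`Inf` for identical images).
#' @export
psnr <- function(reference, image) {
  if (!all(dim(reference) == dim(image))) stop("image shapes differ")
  mse <- mean((as.numeric(reference) - as.numeric(image))^2)
  if (mse == 0) return(Inf)
  10 * log10(255^2 / mse)
}

#' Read an 8-bit image from a PNG/JPEG file
#'
#' @param path file path.
#' @return H x W matrix (grayscale file) or H x W x 3 array, values 0-255.
#' @export
readRasterImage <- function(path) {
  x <- EBImage::readImage(path)
  a <- as.array(x)                       # width x height (x channels)
  a <- .roundHalfUp(a * 255)
  if (length(dim(a)) == 2L) return(t(a))
  a <- a[, , 1:min(3L, dim(a)[3]), drop = FALSE]
  if (dim(a)[3] == 1L) return(t(a[, , 1]))
  aperm(a, c(2, 1, 3))
}

#' Write an 8-bit image (or a binary mask) to a PNG file
#'
#' Binary 0/1 masks are written as 0/255.
#'
#' @param img image matrix/array, values 0-255, or a 0/1 mask matrix.
#' @param path output path (extension selects the format; use `.png`).
#' @export
writeRasterImage <- function(img, path) {
  d <- dim(img)
  if (length(d) == 2L && all(img %in% c(0, 1))) img <- img * 255
  x <- if (length(d) == 2L) t(img) / 255 else aperm(img, c(2, 1, 3)) / 255
  EBImage::writeImage(EBImage::Image(x,
    colormode = if (length(d) == 2L) "Grayscale" else "Color"), path)
  invisible(path)
}
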