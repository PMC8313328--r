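# Shared fixtures, all generated in code.

# Two well-separated Gaussian blobs in 2-D.
makeBlobs <- function(n = 40, sep = 6, seed = 1) {
  set.seed(seed)
  X <- rbind(matrix(stats::rnorm(n), n / 2),
             matrix(stats::rnorm(n) + sep, n / 2))
  y <- factor(rep(c("benign", "malignant"), each = n / 2))
  list(X = X, y = y)
}

# XOR-patterned data: not linearly separable.
makeXor <- function(nPerQuad = 15, seed = 1) {
  set.seed(seed)
  centers <- rbind(c(0, 0), c(4, 4), c(0, 4), c(4, 0))
  X <- do.call(rbind, lapply(1:4, function(i)
    cbind(stats::rnorm(nPerQuad, centers[i, 1], 0.5),
          stats::rnorm(nPerQuad, centers[i, 2], 0.5))))
  y <- factor(rep(c("benign", "benign", "malignant", "malignant"),
                  each = nPerQuad))
  list(X = X, y = y)
}

# Label vectors realizing given confusion counts (positive = "malignant").
countsToLabels <- function(tp, tn, fp, fn) {
  yTrue <- factor(c(rep("malignant", tp + fn), rep("benign", tn + fp)),
                  levels = c("benign", "malignant"))
  yPred <- factor(c(rep("malignant", tp), rep("benign", fn),
                    rep("benign", tn), rep("malignant", fp)),
                  levels = c("benign", "malignant"))
  list(yTrue = yTrue, yPred = yPred)
}

# Rasterized disk mask.
diskMask <- function(radius = 20, pad = 6) {
  n <- 2 * (radius + pad) + 1
  ctr <- radius + pad + 1
  rr <- matrix(seq_len(n), n, n)
  cc <- t(rr)
  ((rr - ctr)^2 + (cc - ctr)^2 <= radius^2) + 0L
}

# Ellipse mask with given semi-axes.
ellipseMask <- function(a, b, pad = 6) {
  n <- 2 * (ceiling(a) + pad) + 1
  ctr <- ceiling(a) + pad + 1
  rr <- matrix(seq_len(n), n, n)
  cc <- t(rr)
  (((cc - ctr) / a)^2 + ((rr - ctr) / b)^2 <= 1) + 0L
}
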