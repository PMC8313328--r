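## Wrapper feature selection driven by the improved optimizer, soft-margin
## SVM training (four kernels), optimizer-tuned hyperparameters and the
## diagnostic metric set.

#' Confusion counts for binary predictions
#'
#' @param yTrue,yPred equal-length vectors (factor, character or 0/1); the
#'   second factor level (or `positive`) is the positive class.
#' @param positive optional explicit positive label.
#' @return named integer vector `c(tp, tn, fp, fn)`.
#' @export
confusionCounts <- function(yTrue, yPred, positive = NULL) {
  if (length(yTrue) != length(yPred)) stop("length mismatch")
  if (length(yTrue) == 0L) stop("empty inputs")
  yTrue <- as.factor(yTrue)
  if (is.null(positive)) positive <- levels(yTrue)[length(levels(yTrue))]
  tp <- sum(yTrue == positive & yPred == positive)
  tn <- sum(yTrue != positive & yPred != positive)
  fp <- sum(yTrue != positive & yPred == positive)
  fn <- sum(yTrue == positive & yPred != positive)
  c(tp = tp, tn = tn, fp = fp, fn = fn)
}

#' Unnormalized correlation fitness of a confusion matrix
#'
#' `(TP*TN - FP*FN) / ((TN+FP)(TP+FP)(TP+FN)(TN+FN))` — the numerator of
#' the Matthews correlation with the *product* (not root-product) of the
#' marginals as denominator. Larger is better; it is the objective the
#' wrapper feature selection maximizes. If any marginal is zero the fitness
#' is defined as 0 (with a warning).
#'
#' @param counts named vector with `tp`, `tn`, `fp`, `fn` (e.g. from
#'   [confusionCounts()]).
#' @return a scalar fitness value.
#' @examples
#' selectionFitness(c(tp = 50, tn = 40, fp = 5, fn = 5))  # 1975/6125625
#' @export
selectionFitness <- function(counts) {
  tp <- counts[["tp"]]; tn <- counts[["tn"]]
  fp <- counts[["fp"]]; fn <- counts[["fn"]]
  den <- (tn + fp) * (tp + fp) * (tp + fn) * (tn + fn)
  if (den == 0) {
    warning("zero marginal in the confusion matrix; fitness defined as 0")
    return(0)
  }
  (tp * tn - fp * fn) / den
}

#' Classification metric report
#'
#' Accuracy, precision and sensitivity are percentages; specificity, the
#' predictive values and the F1 score are fractions; the Matthews
#' correlation coefficient uses the standard square-rooted denominator and
#' lies in `[-1, 1]`.
#'
#' @param yTrue,yPred equal-length binary label vectors.
#' @param positive optional explicit positive label.
#' @return list of class `"metricsReport"` with `acc`, `pr`, `sn` (percent),
#'   `sp`, `ppv`, `npv`, `f1`, `mcc` and `confusion`.
#' @examples
#' evaluateMetrics(c(1, 1, 0, 0), c(1, 0, 0, 0))
#' @export
evaluateMetrics <- function(yTrue, yPred, positive = NULL) {
  cc <- confusionCounts(yTrue, yPred, positive)
  tp <- cc[["tp"]]; tn <- cc[["tn"]]; fp <- cc[["fp"]]; fn <- cc[["fn"]]
  safe <- function(num, den) if (den == 0) NA_real_ else num / den
  mccDen <- sqrt(as.numeric(tp + fp) * (tp + fn) * (tn + fp) * (tn + fn))
  structure(list(
    acc = 100 * (tp + tn) / (tp + tn + fp + fn),
    pr = 100 * safe(tp, tp + fp),
    sn = 100 * safe(tp, tp + fn),
    sp = safe(tn, fp + tn),
    ppv = safe(tp, tp + fp),
    npv = safe(tn, tn + fn),
    f1 = safe(2 * tp, 2 * tp + fp + fn),
    mcc = if (mccDen == 0) NA_real_ else (tp * tn - fp * fn) / mccDen,
    confusion = cc
  ), class = "metricsReport")
}

#' @export
print.metricsReport <- function(x, ...) {
  cat(sprintf("ACC %.2f%%  PR %.2f%%  SN %.2f%%\n", x$acc, x$pr, x$sn))
  cat(sprintf("SP %.4f  PPV %.4f  NPV %.4f  F1 %.4f  MCC %.4f\n",
              x$sp, x$ppv, x$npv, x$f1, x$mcc))
  invisible(x)
}

#' Threshold a continuous optimizer solution into a feature mask
#'
#' Feature d is selected iff `x[d] > 0.5`; if no coordinate exceeds 0.5 the
#' single largest coordinate is selected so the mask is never empty.
#'
#' @param x numeric vector in `[0, 1]`.
#' @return logical vector of the same length.
#' @export
binarizeSolution <- function(x) {
  sel <- x > 0.5
  if (!any(sel)) sel[which.max(x)] <- TRUE
  sel
}

#' Train a soft-margin SVM
#'
#' Thin wrapper over [e1071::svm()] with the four kernels (linear, RBF,
#' polynomial, sigmoid); features are z-scored internally on the training
#' data.
#'
#' @param X numeric matrix or data.frame of features.
#' @param y binary factor of labels.
#' @param kernel one of `"linear"`, `"rbf"`, `"polynomial"`, `"sigmoid"`.
#' @param cost soft-margin penalty C (> 0).
#' @param gamma kernel width for rbf/polynomial/sigmoid (default `1/p`).
#' @param degree polynomial degree.
#' @param coef0 offset for polynomial/sigmoid kernels.
#' @return a fitted `svm` model.
#' @export
trainSvm <- function(X, y, kernel = c("linear", "rbf", "polynomial",
                                      "sigmoid"),
                     cost = 1, gamma = NULL, degree = 3, coef0 = 0) {
  kernel <- match.arg(kernel)
  X <- as.matrix(X)
  if (anyNA(X) || any(!is.finite(X))) stop("features contain NA/non-finite values")
  y <- droplevels(as.factor(y))
  if (nlevels(y) != 2L) stop("y must contain exactly two classes")
  if (cost <= 0) stop("cost must be positive")
  if (is.null(gamma)) gamma <- 1 / ncol(X)
  e1071::svm(X, y,
             kernel = if (kernel == "rbf") "radial" else kernel,
             cost = cost, gamma = gamma, degree = degree, coef0 = coef0,
             scale = TRUE)
}

.stratifiedFolds <- function(y, folds, seed) {
  set.seed(seed)
  fold <- integer(length(y))
  for (lv in levels(y)) {
    idx <- sample(which(y == lv))
    fold[idx] <- rep_len(seq_len(folds), length(idx))
  }
  fold
}

#' Pooled cross-validated fitness of a feature subset / SVM configuration
#'
#' Stratified k-fold cross-validation; out-of-fold predictions are pooled
#' into a single confusion matrix whose [selectionFitness()] is returned.
#' Folds are a pure function of `(y, folds, seed)` so repeated calls during
#' an optimizer run score candidates on identical splits.
#'
#' @param X feature matrix.
#' @param y binary factor.
#' @param kernel,cost,gamma SVM configuration (see [trainSvm()]).
#' @param folds number of folds.
#' @param seed fold seed.
#' @return list with `fitness` and `confusion`.
#' @export
crossValFitness <- function(X, y, kernel = "linear", cost = 1, gamma = NULL,
                            folds = 5L, seed = 1L) {
  X <- as.matrix(X)
  y <- droplevels(as.factor(y))
  fold <- .stratifiedFolds(y, folds, seed)
  pred <- factor(rep(levels(y)[1], length(y)), levels = levels(y))
  for (f in seq_len(folds)) {
    tr <- fold != f
    if (length(unique(y[tr])) < 2L) next
    m <- trainSvm(X[tr, , drop = FALSE], y[tr], kernel = kernel,
                  cost = cost, gamma = gamma)
    pred[!tr] <- stats::predict(m, X[!tr, , drop = FALSE])
  }
  cc <- confusionCounts(y, pred)
  list(fitness = selectionFitness(cc), confusion = cc)
}

#' Wrapper feature selection with the improved optimizer
#'
#' The optimizer searches `[0, 1]^p`; each candidate is thresholded
#' ([binarizeSolution()]) into a feature subset, a linear SVM is scored by
#' pooled stratified cross-validation, and the pooled-confusion
#' [selectionFitness()] is maximized (the optimizer minimizes its
#' negative). Candidate subsets are memoized, so the cost of a run is one
#' cross-validation per *distinct* subset visited.
#'
#' @param X samples x features table.
#' @param y binary factor (both classes present, >= 20 samples).
#' @param nPop,maxIter optimizer budget.
#' @param folds cross-validation folds.
#' @param seed seed driving the optimizer and the folds.
#' @param kernel,cost SVM used inside the wrapper.
#' @return list with `selected` (named logical), `fitness`, `confusion` and
#'   `result` (the [OptimResult-class]).
#' @export
selectFeatures <- function(X, y, nPop = 20L, maxIter = 30L, folds = 5L,
                           seed = 1L, kernel = "linear", cost = 1) {
  X <- as.matrix(X)
  y <- droplevels(as.factor(y))
  if (nlevels(y) != 2L) stop("y must contain two classes")
  if (nrow(X) < 20L) stop("need at least 20 samples")
  p <- ncol(X)
  cache <- new.env(parent = emptyenv())
  score <- function(z) {
    sel <- binarizeSolution(z)
    key <- paste(as.integer(sel), collapse = "")
    hit <- get0(key, envir = cache)
    if (!is.null(hit)) return(hit)
    fit <- crossValFitness(X[, sel, drop = FALSE], y, kernel = kernel,
                           cost = cost, folds = folds, seed = seed)$fitness
    assign(key, -fit, envir = cache)
    -fit
  }
  cfg <- optimizerConfig(nPop = nPop, maxIter = maxIter, lb = 0, ub = 1,
                         d = p, useChaosInit = TRUE, useLevyUpdate = TRUE,
                         seed = seed)
  res <- nnaOptimize(score, cfg)
  sel <- binarizeSolution(bestSolution(res))
  names(sel) <- colnames(X)
  cv <- crossValFitness(X[, sel, drop = FALSE], y, kernel = kernel,
                        cost = cost, folds = folds, seed = seed)
  list(selected = sel, fitness = cv$fitness, confusion = cv$confusion,
       result = res)
}

#' Tune SVM hyperparameters with the improved optimizer
#'
#' Searches `log10(C)` in `[-3, 3]` (and `log10(gamma)` in `[-4, 1]` for
#' the RBF kernel), maximizing the pooled cross-validated
#' [selectionFitness()].
#'
#' @param X feature matrix.
#' @param y binary factor.
#' @param kernel SVM kernel.
#' @param nPop,maxIter optimizer budget.
#' @param folds cross-validation folds.
#' @param seed seed for optimizer and folds.
#' @return list with `kernel`, `cost`, `gamma` (NULL if not tuned),
#'   `fitness` and `result`.
#' @export
tuneSvm <- function(X, y, kernel = "linear", nPop = 15L, maxIter = 20L,
                    folds = 5L, seed = 1L) {
  X <- as.matrix(X)
  y <- droplevels(as.factor(y))
  tuneGamma <- kernel == "rbf"
  d <- if (tuneGamma) 2L else 1L
  lb <- if (tuneGamma) c(-3, -4) else -3
  ub <- if (tuneGamma) c(3, 1) else 3
  cache <- new.env(parent = emptyenv())
  score <- function(z) {
    key <- paste(round(z, 4), collapse = ",")
    hit <- get0(key, envir = cache)
    if (!is.null(hit)) return(hit)
    fit <- crossValFitness(X, y, kernel = kernel, cost = 10^z[1],
                           gamma = if (tuneGamma) 10^z[2] else NULL,
                           folds = folds, seed = seed)$fitness
    assign(key, -fit, envir = cache)
    -fit
  }
  cfg <- optimizerConfig(nPop = nPop, maxIter = maxIter, lb = lb, ub = ub,
                         d = d, useChaosInit = TRUE, useLevyUpdate = TRUE,
                         seed = seed)
  res <- nnaOptimize(score, cfg)
  z <- bestSolution(res)
  list(kernel = kernel, cost = 10^z[1],
       gamma = if (tuneGamma) 10^z[2] else NULL,
       fitness = -bestCost(res), result = res)
}
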