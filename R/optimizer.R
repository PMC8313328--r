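## Neural network algorithm (NNA) and its improved variant (INNA).
##
## Candidate solutions ("patterns") are rows of an nPop x D matrix. A square
## weight matrix W mixes patterns into new ones the way an ANN layer mixes
## inputs; W's columns are kept stochastic (non-negative, summing to 1) so
## every generated pattern is a convex combination of existing ones. The
## improved variant seeds W from a logistic chaos-map orbit and scales the
## weight update by a heavy-tailed Levy draw.

#' Configuration for the NNA/INNA optimizer
#'
#' @param nPop population size (number of candidate patterns).
#' @param maxIter number of generations.
#' @param lb,ub numeric lower/upper bounds, length 1 or D; recycled to the
#'   problem dimension given in `d`.
#' @param d problem dimension.
#' @param gamma0 initial bias modification factor (fraction of coordinates /
#'   weights resampled by the bias operator).
#' @param gammaDecay multiplicative decay applied to gamma each generation.
#' @param chaosRho logistic-map growth parameter used by the chaotic weight
#'   initialization.
#' @param levyTau Levy flight index in (0, 2].
#' @param beta0 initial probability of choosing the bias operator over the
#'   transfer-function operator for a pattern.
#' @param betaDecay multiplicative decay applied to beta each generation.
#' @param levyClip Levy steps are clipped to `[-levyClip, levyClip]` to guard
#'   against rare heavy-tail overflow.
#' @param useChaosInit logical; initialize weights from a logistic-map orbit.
#' @param useLevyUpdate logical; scale weight updates by a Levy draw.
#' @param seed integer seed owned by the optimizer; all stochastic operators
#'   draw from this single stream in a fixed order.
#' @return a validated list of class `"optimizerConfig"`.
#' @examples
#' cfg <- optimizerConfig(nPop = 20, maxIter = 50, lb = -10, ub = 10, d = 2)
#' @export
optimizerConfig <- function(nPop = 100L, maxIter = 100L, lb = -10, ub = 10,
                            d = length(lb), gamma0 = 1, gammaDecay = 0.99,
                            chaosRho = 4, levyTau = 1.5, beta0 = 1,
                            betaDecay = 0.99, levyClip = 10,
                            useChaosInit = FALSE, useLevyUpdate = FALSE,
                            seed = 1L) {
  d <- as.integer(d)
  if (d < 1L) stop("problem dimension must be >= 1")
  lb <- rep_len(as.numeric(lb), d)
  ub <- rep_len(as.numeric(ub), d)
  if (any(!is.finite(lb)) || any(!is.finite(ub)))
    stop("bounds must be finite")
  if (any(lb > ub)) stop("inverted bounds: lb must not exceed ub")
  if (nPop < 2L) stop("nPop must be >= 2")
  if (maxIter < 1L) stop("maxIter must be >= 1")
  if (gammaDecay <= 0 || gammaDecay >= 1) stop("gammaDecay must be in (0, 1)")
  if (levyTau <= 0 || levyTau > 2) stop("levyTau must be in (0, 2]")
  structure(list(
    nPop = as.integer(nPop), maxIter = as.integer(maxIter),
    lb = lb, ub = ub, d = d,
    gamma0 = gamma0, gammaDecay = gammaDecay, chaosRho = chaosRho,
    levyTau = levyTau, beta0 = beta0, betaDecay = betaDecay,
    levyClip = levyClip,
    useChaosInit = isTRUE(useChaosInit), useLevyUpdate = isTRUE(useLevyUpdate),
    seed = as.integer(seed)
  ), class = "optimizerConfig")
}

.clipBox <- function(x, lb, ub) {
  pmin(pmax(x, rep(lb, each = nrow(x))), rep(ub, each = nrow(x)))
}

.normalizeCols <- function(W) {
  s <- colSums(W)
  zero <- s <= 0
  if (any(zero)) {
    W[, zero] <- 1 / nrow(W)
    s[zero] <- 1
  }
  sweep(W, 2L, s, "/")
}

#' Initialize a pattern population uniformly within box bounds
#'
#' Draws from the current RNG stream; callers wanting reproducibility seed
#' beforehand (as [nnaOptimize()] does).
#'
#' @param config an [optimizerConfig()].
#' @return nPop x d numeric matrix, each row one candidate pattern.
#' @export
initializePopulation <- function(config) {
  n <- config$nPop; d <- config$d
  u <- matrix(stats::runif(n * d), n, d)
  sweep(sweep(u, 2L, config$ub - config$lb, "*"), 2L, config$lb, "+")
}

#' One step of the logistic chaos map
#'
#' The recurrence `beta' = rho * beta * (1 - beta)`; with `rho = 4` the orbit
#' is chaotic on `[0, 1]` and is used to diversify weight initialization.
#'
#' @param beta current state in `[0, 1]`.
#' @param rho growth parameter.
#' @return the next state.
#' @export
logisticMapStep <- function(beta, rho = 4) {
  if (any(beta < 0 | beta > 1)) stop("beta must lie in [0, 1]")
  rho * beta * (1 - beta)
}

#' Initialize the inter-pattern weight matrix
#'
#' In uniform mode, entries are U(0,1). In chaotic mode, each row is filled
#' with successive iterates of the logistic map started from a random (or
#' supplied) value in (0, 1); with bounds 0 and 1 on the weights, the map
#' iterate is the weight itself. Columns are renormalized to sum to 1 so each
#' generated pattern is a convex combination of existing patterns.
#'
#' @param nPop number of patterns (matrix is nPop x nPop).
#' @param mode `"uniform"` or `"chaotic"`.
#' @param chaosRho logistic-map parameter for chaotic mode.
#' @param beta0 optional numeric vector (length nPop) of starting states for
#'   chaotic mode; by default drawn U(0,1). Exposed for testing the orbit.
#' @return column-stochastic nPop x nPop matrix with entries in `[0, 1]`.
#' @export
initializeWeights <- function(nPop, mode = c("uniform", "chaotic"),
                              chaosRho = 4, beta0 = NULL) {
  mode <- match.arg(mode)
  if (nPop < 2L) stop("nPop must be >= 2")
  if (mode == "uniform") {
    W <- matrix(stats::runif(nPop * nPop), nPop, nPop)
  } else {
    if (is.null(beta0)) beta0 <- stats::runif(nPop)
    beta0 <- rep_len(beta0, nPop)
    W <- matrix(0, nPop, nPop)
    for (i in seq_len(nPop)) {
      b <- beta0[i]
      for (j in seq_len(nPop)) {
        b <- logisticMapStep(b, chaosRho)
        W[i, j] <- b
      }
    }
  }
  .normalizeCols(W)
}

#' Generate new patterns by mixing the population through the weight matrix
#'
#' New pattern j is the weighted sum over patterns i of `W[i, j] * X[i, ]`
#' (a convex combination, since columns of W sum to 1); the population then
#' moves to `X + Xnew`, clipped to the box.
#'
#' @param X nPop x d pattern matrix.
#' @param W column-stochastic nPop x nPop weight matrix.
#' @param lb,ub box bounds (length d).
#' @return list with `values` (the clipped updated population) and `xNew`
#'   (the raw mixed patterns).
#' @export
generateNewPatterns <- function(X, W, lb, ub) {
  if (nrow(X) != nrow(W)) stop("population and weight matrix sizes differ")
  xNew <- crossprod(W, X)   # row j = sum_i W[i,j] * X[i,]
  list(values = .clipBox(X + xNew, lb, ub), xNew = xNew)
}

#' Mantegna scale parameter for a Levy flight index
#'
#' @param tau Levy index in (0, 2].
#' @return the standard deviation sigma of the numerator Gaussian.
#' @export
levySigma <- function(tau) {
  if (tau <= 0 || tau > 2) stop("tau must be in (0, 2]")
  ((gamma(1 + tau) * sin(pi * tau / 2)) /
     (gamma((1 + tau) / 2) * tau * 2^((tau - 1) / 2)))^(1 / tau)
}

#' Draw Levy-flight step sizes by Mantegna's algorithm
#'
#' `step = A / |B|^(1/tau)` with `A ~ N(0, sigma^2)`, `B ~ N(0, 1)`, giving a
#' symmetric heavy-tailed distribution. Steps are clipped to
#' `[-clip, clip]`.
#'
#' @param n number of draws.
#' @param tau Levy index.
#' @param clip clipping bound for the heavy tail.
#' @return numeric vector of `n` step sizes.
#' @export
levyDraw <- function(n = 1L, tau = 1.5, clip = 10) {
  s <- levySigma(tau)
  a <- stats::rnorm(n, 0, s)
  b <- stats::rnorm(n)
  pmin(pmax(a / abs(b)^(1 / tau), -clip), clip)
}

#' Move every weight vector toward the target pattern's weights
#'
#' Base rule: `W[, i] <- W[, i] + 2 * rand * (W[, target] - W[, i])`. When
#' `levy` is supplied the step is additionally scaled by the magnitude of a
#' fresh Levy draw per weight vector: the Levy factor modulates the step
#' *size* along the already-directed move toward the target's weights, so its
#' sign is dropped (a signed zero-mean factor would turn the contraction into
#' a random walk). Entries are clipped to `[0, 1]` and columns renormalized.
#'
#' @param W weight matrix.
#' @param targetIndex column index of the target pattern's weight vector.
#' @param levy `NULL` for the base rule, or a list with `tau` and `clip` for
#'   the Levy-scaled rule.
#' @param rand optional numeric vector of per-column step factors (test hook);
#'   drawn U(0,1) when `NULL`.
#' @return updated column-stochastic weight matrix.
#' @export
updateWeights <- function(W, targetIndex, levy = NULL, rand = NULL) {
  n <- ncol(W)
  if (targetIndex < 1L || targetIndex > n) stop("invalid target index")
  if (is.null(rand)) rand <- stats::runif(n)
  rand <- rep_len(rand, n)
  scale <- 2 * rand
  if (!is.null(levy))
    scale <- scale * abs(levyDraw(n, tau = levy$tau, clip = levy$clip))
  wT <- W[, targetIndex]
  W <- W + sweep(wT - W, 2L, scale, "*")
  W <- pmin(pmax(W, 0), 1)
  .normalizeCols(W)
}

#' Bias operator: random resampling of coordinates and weights
#'
#' For each pattern with `rand <= gamma` (all patterns when `gate = FALSE`),
#' `round(d * gamma)` randomly chosen coordinates are resampled uniformly
#' within the bounds and `round(nPop * gamma)` randomly chosen entries of
#' that pattern's weight vector are resampled U(0,1). Columns of the weight
#' matrix are renormalized afterwards.
#'
#' @param X pattern matrix.
#' @param W weight matrix.
#' @param gamma modification factor in `[0, 1]`.
#' @param lb,ub box bounds.
#' @param gate logical; apply the per-pattern `rand <= gamma` gate. The main
#'   loop gates patterns by beta instead and calls with `gate = FALSE`.
#' @return list with updated `values` and `W`.
#' @export
biasOperator <- function(X, W, gamma, lb, ub, gate = TRUE) {
  stopifnot(gamma >= 0, gamma <= 1)
  n <- nrow(X); d <- ncol(X)
  nB <- round(d * gamma)
  nWb <- round(n * gamma)
  for (i in seq_len(n)) {
    if (gate && stats::runif(1) > gamma) next
    if (nB > 0L) {
      idx <- sample.int(d, nB)
      X[i, idx] <- lb[idx] + (ub[idx] - lb[idx]) * stats::runif(nB)
    }
    if (nWb > 0L) {
      widx <- sample.int(n, nWb)
      W[widx, i] <- stats::runif(nWb)
    }
  }
  list(values = X, W = .normalizeCols(W))
}

#' Transfer-function operator: move patterns toward the target solution
#'
#' `X[i, ] <- X[i, ] + 2 * rand_i * (target - X[i, ])` with a fresh scalar
#' `rand_i` per pattern, clipped to the box.
#'
#' @param X pattern matrix.
#' @param target the target (best) decision vector.
#' @param lb,ub box bounds.
#' @param rand optional per-pattern step factors (test hook).
#' @return updated pattern matrix.
#' @export
transferFunction <- function(X, target, lb, ub, rand = NULL) {
  if (length(target) != ncol(X)) stop("target dimension mismatch")
  n <- nrow(X)
  if (is.null(rand)) rand <- stats::runif(n)
  rand <- rep_len(rand, n)
  X <- X + (2 * rand) * (matrix(target, n, length(target), byrow = TRUE) - X)
  .clipBox(X, lb, ub)
}

#' Geometric decay of the modification factor
#'
#' @param gamma current factor.
#' @param decay multiplicative decay (default 0.99).
#' @return `decay * gamma`.
#' @export
decayGamma <- function(gamma, decay = 0.99) {
  if (gamma < 0) stop("gamma must be non-negative")
  decay * gamma
}

.evalPopulation <- function(objective, X) {
  cost <- apply(X, 1L, objective)
  bad <- which(!is.finite(cost))
  if (length(bad))
    stop("objective returned a non-finite value for pattern ", bad[1])
  cost
}

#' Run the NNA / INNA optimizer
#'
#' Minimizes `objective` over the box in `config`. Each generation:
#' patterns are mixed through the weight matrix
#' ([generateNewPatterns()]); the weight matrix moves toward the target's
#' weights ([updateWeights()], Levy-scaled for the improved variant); with
#' probability `beta` the generation is an exploration generation, in which
#' each pattern is bias-perturbed with probability `gamma`
#' ([biasOperator()]); every pattern not bias-perturbed moves toward the
#' target by the transfer function ([transferFunction()]); costs are
#' evaluated and `gamma` and `beta` decay geometrically. The best-ever
#' solution is kept in the population (elitism), so the recorded history is
#' non-increasing.
#'
#' All randomness comes from a single stream seeded with `config$seed`; per
#' generation the draw order is fixed (weight-update factors, Levy factors,
#' generation gate, per-pattern gates, transfer factors, bias resampling), so
#' runs are bit-reproducible per seed.
#'
#' @param objective function mapping a length-d numeric vector to a finite
#'   scalar cost.
#' @param config an [optimizerConfig()]; set `useChaosInit` and
#'   `useLevyUpdate` for the improved variant.
#' @return an [OptimResult-class] object.
#' @examples
#' cfg <- optimizerConfig(nPop = 30, maxIter = 60, lb = -10, ub = 10, d = 2,
#'                        seed = 7)
#' res <- nnaOptimize(function(x) sum(x^2), cfg)
#' bestCost(res)
#' @export
nnaOptimize <- function(objective, config) {
  stopifnot(inherits(config, "optimizerConfig"))
  set.seed(config$seed)
  n <- config$nPop; d <- config$d
  lb <- config$lb; ub <- config$ub
  levy <- if (config$useLevyUpdate)
    list(tau = config$levyTau, clip = config$levyClip) else NULL

  X <- initializePopulation(config)
  W <- initializeWeights(n,
    mode = if (config$useChaosInit) "chaotic" else "uniform",
    chaosRho = config$chaosRho)
  cost <- .evalPopulation(objective, X)
  evals <- n
  bestIdx <- which.min(cost)
  bestX <- X[bestIdx, ]
  bestCost <- cost[bestIdx]
  gamma <- config$gamma0
  beta <- config$beta0
  history <- numeric(config$maxIter)

  for (t in seq_len(config$maxIter)) {
    targetIdx <- which.min(cost)
    xTarget <- X[targetIdx, ]

    X <- generateNewPatterns(X, W, lb, ub)$values
    W <- updateWeights(W, targetIdx, levy = levy)

    biasGeneration <- stats::runif(1) <= beta
    biased <- biasGeneration & (stats::runif(n) <= gamma)
    nB <- round(d * gamma)
    nWb <- round(n * gamma)
    tfRand <- stats::runif(n)
    for (i in seq_len(n)) {
      if (biased[i]) {
        if (nB > 0L) {
          idx <- sample.int(d, nB)
          X[i, idx] <- lb[idx] + (ub[idx] - lb[idx]) * stats::runif(nB)
        }
        if (nWb > 0L) W[sample.int(n, nWb), i] <- stats::runif(nWb)
      } else {
        X[i, ] <- pmin(pmax(X[i, ] + 2 * tfRand[i] * (xTarget - X[i, ]),
                            lb), ub)
      }
    }
    W <- .normalizeCols(W)

    cost <- .evalPopulation(objective, X)
    evals <- evals + n
    curIdx <- which.min(cost)
    if (cost[curIdx] < bestCost) {
      bestCost <- cost[curIdx]
      bestX <- X[curIdx, ]
    } else {
      worst <- which.max(cost)
      X[worst, ] <- bestX
      cost[worst] <- bestCost
    }
    history[t] <- bestCost

    gamma <- decayGamma(gamma, config$gammaDecay)
    beta <- decayGamma(beta, config$betaDecay)
  }

  new("OptimResult",
      bestSolution = bestX, bestCost = bestCost, history = history,
      evaluations = as.integer(evals), config = unclass(config))
}
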