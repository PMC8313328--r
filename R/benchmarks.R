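## Six standard box-constrained test functions used to validate the
## optimizer, plus a study harness reporting Min/Max/Mean/Std of final best
## costs over repeated seeded runs.

.benchmarkTable <- list(
  rosenbrock = list(bounds = c(-30, 30), minimizer = function(d) rep(1, d)),
  sum_squares = list(bounds = c(-10, 10), minimizer = function(d) rep(0, d)),
  step2 = list(bounds = c(-100, 100), minimizer = function(d) rep(-0.5, d)),
  schwefel_2_22 = list(bounds = c(-10, 10), minimizer = function(d) rep(0, d)),
  schwefel_1_2 = list(bounds = c(-100, 100), minimizer = function(d) rep(0, d)),
  chung_reynolds = list(bounds = c(-100, 100), minimizer = function(d) rep(0, d))
)

#' Names of the available benchmark functions
#' @return character vector of the six function names.
#' @export
benchmarkNames <- function() names(.benchmarkTable)

#' Evaluate a benchmark test function
#'
#' The six functions are the classic Rosenbrock
#' `sum(100 (x_{i+1} - x_i^2)^2 + (x_i - 1)^2)`, Sum Squares `sum(i x_i^2)`,
#' Step 2 `sum((x_i + 0.5)^2)`, Schwefel 2.22 `sum|x_i| + prod|x_i|`,
#' Schwefel 1.2 `sum_i (sum_{j<=i} x_j)^2` and Chung Reynolds
#' `(sum x_i^2)^2`. All have minimum 0 (at all-ones for Rosenbrock, all -0.5
#' for Step 2, the origin otherwise).
#'
#' Schwefel 2.22 is sometimes printed with a minus between the sum and
#' product terms; that variant (whose minimum is not 0) is available with
#' `printedForm = TRUE`.
#'
#' @param name one of [benchmarkNames()].
#' @param x numeric decision vector.
#' @param printedForm logical; for `schwefel_2_22` only, use the
#'   sum-minus-product variant.
#' @return the function value (a scalar).
#' @examples
#' evaluateBenchmark("rosenbrock", c(1, 1, 1))  # 0
#' evaluateBenchmark("sum_squares", c(1, 1, 1)) # 6
#' @export
evaluateBenchmark <- function(name, x, printedForm = FALSE) {
  name <- match.arg(name, benchmarkNames())
  if (length(x) < 1L) stop("x must have at least one element")
  b <- .benchmarkTable[[name]]$bounds
  if (any(x < b[1] - 1e-9) || any(x > b[2] + 1e-9))
    warning("x lies outside the canonical bounds [", b[1], ", ", b[2], "]")
  switch(name,
    rosenbrock = {
      if (length(x) < 2L) stop("rosenbrock needs dimension >= 2")
      d <- length(x)
      sum(100 * (x[-1] - x[-d]^2)^2 + (x[-d] - 1)^2)
    },
    sum_squares = sum(seq_along(x) * x^2),
    step2 = sum((x + 0.5)^2),
    schwefel_2_22 = if (printedForm) sum(abs(x)) - prod(abs(x))
                    else sum(abs(x)) + prod(abs(x)),
    schwefel_1_2 = sum(cumsum(x)^2),
    chung_reynolds = sum(x^2)^2
  )
}

#' Canonical bounds of a benchmark function
#' @param name one of [benchmarkNames()].
#' @return numeric length-2 vector `c(lower, upper)`.
#' @export
benchmarkBounds <- function(name) {
  name <- match.arg(name, benchmarkNames())
  .benchmarkTable[[name]]$bounds
}

#' Canonical minimizer of a benchmark function
#' @param name one of [benchmarkNames()].
#' @param d dimension.
#' @return the known global minimizer (function value 0).
#' @export
benchmarkMinimizer <- function(name, d = 30L) {
  name <- match.arg(name, benchmarkNames())
  .benchmarkTable[[name]]$minimizer(d)
}

#' Run a Min/Max/Mean/Std optimizer study on the benchmark suite
#'
#' Each (algorithm, function) cell runs the optimizer for `runs` independent
#' seeds (derived as `seed + run - 1`) and summarizes the final best costs.
#' `"nna"` is the base algorithm; `"inna"` enables chaotic weight
#' initialization and Levy-flight weight updates.
#'
#' @param algorithms character vector from `c("nna", "inna")`.
#' @param functions character vector from [benchmarkNames()], or `"all"`.
#' @param runs number of independent runs per cell (>= 2).
#' @param dim problem dimension.
#' @param nPop,maxIter population size and generations per run.
#' @param seed base seed; run r of every cell uses `seed + r - 1`.
#' @return a data.frame with one row per cell (`algorithm`, `fn`, `min`,
#'   `max`, `mean`, `std`, `runs`) and the per-run final costs in
#'   `attr(, "costs")` (a named list).
#' @examples
#' \donttest{
#' runStudy("nna", "sum_squares", runs = 3, dim = 5, nPop = 20, maxIter = 30)
#' }
#' @export
runStudy <- function(algorithms = c("nna", "inna"), functions = "all",
                     runs = 20L, dim = 30L, nPop = 100L, maxIter = 100L,
                     seed = 1L) {
  algorithms <- match.arg(tolower(algorithms), c("nna", "inna"),
                          several.ok = TRUE)
  if (identical(functions, "all")) functions <- benchmarkNames()
  functions <- match.arg(functions, benchmarkNames(), several.ok = TRUE)
  if (runs < 2L) stop("runs must be >= 2")
  rows <- list()
  costs <- list()
  for (algo in algorithms) {
    for (fn in functions) {
      b <- benchmarkBounds(fn)
      finals <- vapply(seq_len(runs), function(r) {
        cfg <- optimizerConfig(
          nPop = nPop, maxIter = maxIter, lb = b[1], ub = b[2], d = dim,
          useChaosInit = algo == "inna", useLevyUpdate = algo == "inna",
          seed = seed + r - 1L)
        bestCost(nnaOptimize(function(x) evaluateBenchmark(fn, x), cfg))
      }, numeric(1))
      key <- paste(algo, fn, sep = ".")
      costs[[key]] <- finals
      rows[[key]] <- data.frame(
        algorithm = algo, fn = fn, min = min(finals), max = max(finals),
        mean = mean(finals), std = stats::sd(finals), runs = runs,
        stringsAsFactors = FALSE)
    }
  }
  out <- do.call(rbind, c(rows, list(make.row.names = FALSE)))
  attr(out, "costs") <- costs
  out
}
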