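#' @import methods
NULL

#' Result of a population-optimizer run
#'
#' Container returned by [nnaOptimize()]. The history slot records the
#' best-ever objective value at the end of each generation, so it is
#' non-increasing by construction; `bestCost` equals its final entry.
#'
#' @slot bestSolution numeric vector, the best decision vector found.
#' @slot bestCost numeric(1), objective value at `bestSolution`.
#' @slot history numeric vector of per-generation best-ever costs.
#' @slot evaluations integer(1), number of objective evaluations performed.
#' @slot config list, the [optimizerConfig()] used for the run.
#'
#' @aliases OptimResult
#' @exportClass OptimResult
setClass("OptimResult",
  representation(
    bestSolution = "numeric",
    bestCost = "numeric",
    history = "numeric",
    evaluations = "integer",
    config = "list"
  )
)

setValidity("OptimResult", function(object) {
  msg <- NULL
  if (length(object@bestCost) != 1L)
    msg <- c(msg, "bestCost must be a single value")
  if (length(object@history) > 0L) {
    if (any(diff(object@history) > 1e-12))
      msg <- c(msg, "history must be non-increasing")
    if (abs(object@bestCost - object@history[length(object@history)]) > 1e-12)
      msg <- c(msg, "bestCost must equal the last history entry")
  }
  if (is.null(msg)) TRUE else msg
})

#' @describeIn OptimResult-class best decision vector
#' @param object an `OptimResult`
#' @export
setGeneric("bestSolution", function(object) standardGeneric("bestSolution"))

#' @describeIn OptimResult-class best objective value
#' @export
setGeneric("bestCost", function(object) standardGeneric("bestCost"))

#' @describeIn OptimResult-class per-generation best-ever cost trace
#' @export
setGeneric("costHistory", function(object) standardGeneric("costHistory"))

#' @rdname OptimResult-class
#' @export
setMethod("bestSolution", "OptimResult", function(object) object@bestSolution)

#' @rdname OptimResult-class
#' @export
setMethod("bestCost", "OptimResult", function(object) object@bestCost)

#' @rdname OptimResult-class
#' @export
setMethod("costHistory", "OptimResult", function(object) object@history)

setMethod("show", "OptimResult", function(object) {
  cat("OptimResult:", length(object@bestSolution), "decision variables\n")
  cat("  best cost   :", format(object@bestCost, digits = 6), "\n")
  cat("  generations :", length(object@history), "\n")
  cat("  evaluations :", object@evaluations, "\n")
})

#' A synthetic dermoscopy-like sample
#'
#' One generated lesion image together with its exact ground-truth mask, a
#' benign/malignant label derived from the generating shape parameters, and
#' the [lesionSpec()] that produced it.
#'
#' @slot image integer array, height x width x 3, values 0-255.
#' @slot mask integer matrix of 0/1, same height/width as `image`.
#' @slot label character(1), `"benign"` or `"malignant"`.
#' @slot spec list, the generating [lesionSpec()].
#'
#' @aliases LesionSample
#' @exportClass LesionSample
setClass("LesionSample",
  representation(
    image = "array",
    mask = "matrix",
    label = "character",
    spec = "list"
  )
)

setValidity("LesionSample", function(object) {
  msg <- NULL
  d <- dim(object@image)
  if (length(d) != 3L || d[3] != 3L)
    msg <- c(msg, "image must be height x width x 3")
  if (!all(dim(object@mask) == d[1:2]))
    msg <- c(msg, "mask must match image height/width")
  if (!all(object@mask %in% c(0L, 1L)))
    msg <- c(msg, "mask must be binary 0/1")
  if (min(object@image) < 0 || max(object@image) > 255)
    msg <- c(msg, "image values must lie in [0, 255]")
  if (!object@label %in% c("benign", "malignant"))
    msg <- c(msg, "label must be 'benign' or 'malignant'")
  if (is.null(msg)) TRUE else msg
})

#' @describeIn LesionSample-class the RGB image array (0-255)
#' @param object a `LesionSample`
#' @export
setGeneric("lesionImage", function(object) standardGeneric("lesionImage"))

#' @describeIn LesionSample-class the ground-truth binary mask
#' @export
setGeneric("lesionMask", function(object) standardGeneric("lesionMask"))

#' @describeIn LesionSample-class the class label
#' @export
setGeneric("lesionLabel", function(object) standardGeneric("lesionLabel"))

#' @rdname LesionSample-class
#' @export
setMethod("lesionImage", "LesionSample", function(object) object@image)

#' @rdname LesionSample-class
#' @export
setMethod("lesionMask", "LesionSample", function(object) object@mask)

#' @rdname LesionSample-class
#' @export
setMethod("lesionLabel", "LesionSample", function(object) object@label)

setMethod("show", "LesionSample", function(object) {
  d <- dim(object@image)
  cat("LesionSample:", d[1], "x", d[2], "RGB,", object@label, "\n")
  cat("  lesion area:", sum(object@mask), "px (",
      round(100 * mean(object@mask), 1), "% of image )\n")
})
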