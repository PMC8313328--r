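## End-to-end orchestration: preprocess -> segment -> extract features ->
## select -> tune/train -> evaluate, with a single global seed from which
## every stage's seed is derived.

#' Derive a module seed from the global pipeline seed
#'
#' Each stage draws its seed as a deterministic hash of (global seed,
#' module name), so adding a stage never perturbs another stage's stream.
#'
#' @param globalSeed integer.
#' @param module module name.
#' @return a positive integer below 2^31.
#' @export
moduleSeed <- function(globalSeed, module) {
  h <- sum(utf8ToInt(module) * seq_along(utf8ToInt(module)))
  as.integer((as.numeric(globalSeed) * 7919 + h * 104729) %% 2147483647) + 1L
}

#' Assemble and validate a pipeline configuration
#'
#' @param seed global seed; all stage seeds derive from it via
#'   [moduleSeed()].
#' @param nSamples number of synthetic samples generated when no input
#'   directory is given.
#' @param imageSize synthetic image size.
#' @param medianWindow median-filter window (odd).
#' @param segmentation a [segmentationConfig()] (stage seed is overridden).
#' @param kernel SVM kernel for the final classifier.
#' @param tune logical; tune the SVM cost with the optimizer.
#' @param selectionPop,selectionIter optimizer budget for feature selection.
#' @param tunePop,tuneIter optimizer budget for hyperparameter tuning.
#' @param folds cross-validation folds used by selection and tuning.
#' @param trainFraction training share of the stratified split.
#' @param inputDir optional directory of PNG images plus a `labels.csv`
#'   (columns `image`, `label`); when `NULL` synthetic data is generated.
#' @param outDir optional output directory for stage artifacts.
#' @return list of class `"pipelineConfig"`.
#' @export
pipelineConfig <- function(seed = 1L, nSamples = 20L,
                           imageSize = c(128L, 128L), medianWindow = 3L,
                           segmentation = segmentationConfig(),
                           kernel = "linear", tune = TRUE,
                           selectionPop = 15L, selectionIter = 20L,
                           tunePop = 10L, tuneIter = 10L, folds = 5L,
                           trainFraction = 0.8, inputDir = NULL,
                           outDir = NULL) {
  stopifnot(inherits(segmentation, "segmentationConfig"))
  if (trainFraction <= 0 || trainFraction >= 1)
    stop("trainFraction must lie in (0, 1)")
  if (medianWindow %% 2L == 0L) stop("medianWindow must be odd")
  structure(list(
    seed = as.integer(seed), nSamples = as.integer(nSamples),
    imageSize = rep_len(as.integer(imageSize), 2L),
    medianWindow = as.integer(medianWindow), segmentation = segmentation,
    kernel = kernel, tune = isTRUE(tune),
    selectionPop = as.integer(selectionPop),
    selectionIter = as.integer(selectionIter),
    tunePop = as.integer(tunePop), tuneIter = as.integer(tuneIter),
    folds = as.integer(folds), trainFraction = trainFraction,
    inputDir = inputDir, outDir = outDir
  ), class = "pipelineConfig")
}

.knownConfigKeys <- c("seed", "nSamples", "imageSize", "medianWindow",
                      "segmentation", "kernel", "tune", "selectionPop",
                      "selectionIter", "tunePop", "tuneIter", "folds",
                      "trainFraction", "inputDir", "outDir")

#' Load a pipeline configuration from a YAML or JSON file
#'
#' Missing keys take their defaults; unknown keys are rejected with the
#' offending field named. The `segmentation` key may hold a nested mapping
#' with [segmentationConfig()] fields.
#'
#' @param path file path (`.yaml`/`.yml` or `.json`); an empty file yields
#'   all defaults.
#' @return a [pipelineConfig()].
#' @export
loadPipelineConfig <- function(path) {
  raw <- if (grepl("\\.json$", path, ignore.case = TRUE))
    jsonlite::read_json(path, simplifyVector = TRUE)
  else yaml::read_yaml(path)
  if (is.null(raw)) raw <- list()
  unknown <- setdiff(names(raw), .knownConfigKeys)
  if (length(unknown))
    stop("unknown configuration field(s): ", paste(unknown, collapse = ", "))
  if (!is.null(raw$segmentation)) {
    segUnknown <- setdiff(names(raw$segmentation),
                          names(formals(segmentationConfig)))
    if (length(segUnknown))
      stop("unknown segmentation field(s): ",
           paste0("segmentation.", segUnknown, collapse = ", "))
    raw$segmentation <- do.call(segmentationConfig, raw$segmentation)
  }
  do.call(pipelineConfig, raw)
}

.readInputDir <- function(dir) {
  labFile <- file.path(dir, "labels.csv")
  if (!file.exists(labFile)) stop("labels.csv not found in ", dir)
  lab <- utils::read.csv(labFile, stringsAsFactors = FALSE)
  lapply(seq_len(nrow(lab)), function(i) {
    list(id = lab$image[i],
         image = readRasterImage(file.path(dir, lab$image[i])),
         label = lab$label[i])
  })
}

#' Run the full diagnosis pipeline
#'
#' Stages: (1) preprocessing (median filter + contrast stretch), (2) lesion
#' segmentation, (3) extraction of the 19 descriptors, (4) one stratified
#' train/test split, (5) wrapper feature selection on the training split,
#' (6) optimizer tuning and training of the SVM on the selected features,
#' (7) evaluation on the held-out split. Identical `(inputs, config, seed)`
#' give byte-identical metric reports.
#'
#' @param config a [pipelineConfig()].
#' @param samples optional list of [LesionSample-class] objects (overrides
#'   both `inputDir` and synthetic generation).
#' @return list with `metrics` (a `metricsReport` for the held-out split),
#'   `selection`, `svm` (tuned configuration), `model`, `features`
#'   (data.frame with labels and split membership) and `manifest` (config
#'   echo, seeds, per-stage timings, artifact paths).
#' @export
runPipeline <- function(config = pipelineConfig(), samples = NULL) {
  stopifnot(inherits(config, "pipelineConfig"))
  timings <- c()
  clock <- function(expr) {
    t0 <- Sys.time()
    v <- force(expr)
    attr(v, ".elapsed") <- as.numeric(Sys.time() - t0)
    v
  }
  out <- config$outDir
  if (!is.null(out)) dir.create(out, recursive = TRUE, showWarnings = FALSE)
  artifacts <- list()

  # --- acquisition -------------------------------------------------------
  t0 <- Sys.time()
  if (is.null(samples)) {
    samples <- if (!is.null(config$inputDir)) .readInputDir(config$inputDir)
    else {
      batt <- generateLesionBattery(config$nSamples,
                                    seed = moduleSeed(config$seed, "synth"),
                                    size = config$imageSize)
      lapply(seq_along(batt), function(i)
        list(id = sprintf("synthetic_%03d", i),
             image = lesionImage(batt[[i]]), label = lesionLabel(batt[[i]])))
    }
  } else {
    samples <- lapply(seq_along(samples), function(i) {
      s <- samples[[i]]
      if (methods::is(s, "LesionSample"))
        list(id = sprintf("sample_%03d", i), image = lesionImage(s),
             label = lesionLabel(s))
      else s
    })
  }
  labels <- factor(vapply(samples, `[[`, "", "label"),
                   levels = c("benign", "malignant"))
  if (nlevels(droplevels(labels)) < 2L)
    stop("pipeline stage acquisition: need both classes in the input labels")
  timings["acquisition"] <- as.numeric(Sys.time() - t0)

  # --- preprocessing -----------------------------------------------------
  t0 <- Sys.time()
  cleaned <- lapply(samples, function(s) {
    img <- medianFilterImage(s$image, config$medianWindow)
    stretchContrast(img)
  })
  timings["preprocess"] <- as.numeric(Sys.time() - t0)

  # --- segmentation ------------------------------------------------------
  t0 <- Sys.time()
  segCfg <- config$segmentation
  segCfg$seed <- moduleSeed(config$seed, "segmentation")
  masks <- lapply(cleaned, segmentLesion, config = segCfg)
  timings["segment"] <- as.numeric(Sys.time() - t0)

  # --- features ----------------------------------------------------------
  t0 <- Sys.time()
  feat <- t(vapply(seq_along(cleaned), function(i)
    extractFeatures(cleaned[[i]], masks[[i]]),
    numeric(length(featureNames()))))
  featDf <- as.data.frame(feat)
  timings["features"] <- as.numeric(Sys.time() - t0)

  # --- split -------------------------------------------------------------
  set.seed(moduleSeed(config$seed, "split"))
  trainIdx <- logical(length(labels))
  for (lv in levels(labels)) {
    idx <- sample(which(labels == lv))
    nTr <- max(1L, round(config$trainFraction * length(idx)))
    trainIdx[idx[seq_len(nTr)]] <- TRUE
  }
  if (all(trainIdx)) trainIdx[which(labels == labels[1])[1]] <- FALSE

  # --- selection ---------------------------------------------------------
  t0 <- Sys.time()
  selSeed <- moduleSeed(config$seed, "selection")
  sel <- selectFeatures(featDf[trainIdx, , drop = FALSE], labels[trainIdx],
                        nPop = config$selectionPop,
                        maxIter = config$selectionIter,
                        folds = config$folds, seed = selSeed)
  timings["select"] <- as.numeric(Sys.time() - t0)

  # --- tune + train ------------------------------------------------------
  t0 <- Sys.time()
  Xtr <- as.matrix(featDf[trainIdx, sel$selected, drop = FALSE])
  tuneSeed <- moduleSeed(config$seed, "tuning")
  svmCfg <- if (config$tune)
    tuneSvm(Xtr, labels[trainIdx], kernel = config$kernel,
            nPop = config$tunePop, maxIter = config$tuneIter,
            folds = config$folds, seed = tuneSeed)
  else list(kernel = config$kernel, cost = 1, gamma = NULL)
  model <- trainSvm(Xtr, labels[trainIdx], kernel = config$kernel,
                    cost = svmCfg$cost, gamma = svmCfg$gamma)
  timings["train"] <- as.numeric(Sys.time() - t0)

  # --- evaluate ----------------------------------------------------------
  t0 <- Sys.time()
  Xte <- as.matrix(featDf[!trainIdx, sel$selected, drop = FALSE])
  pred <- stats::predict(model, Xte)
  metrics <- evaluateMetrics(labels[!trainIdx], pred)
  timings["evaluate"] <- as.numeric(Sys.time() - t0)

  featDf$label <- labels
  featDf$split <- ifelse(trainIdx, "train", "test")
  featDf$id <- vapply(samples, `[[`, "", "id")

  if (!is.null(out)) {
    for (i in seq_along(masks))
      artifacts[[paste0("mask_", samples[[i]]$id)]] <-
        writeRasterImage(masks[[i]],
                         file.path(out, paste0(samples[[i]]$id, "_mask.png")))
    utils::write.csv(featDf, file.path(out, "features.csv"),
                     row.names = FALSE)
    artifacts$features <- file.path(out, "features.csv")
    jsonlite::write_json(list(selected = names(sel$selected)[sel$selected],
                              fitness = sel$fitness),
                         file.path(out, "selection.json"), auto_unbox = TRUE)
    artifacts$selection <- file.path(out, "selection.json")
    jsonlite::write_json(metrics[c("acc", "pr", "sn", "sp", "ppv", "npv",
                                   "f1", "mcc")],
                         file.path(out, "metrics.json"), auto_unbox = TRUE,
                         digits = NA)
    artifacts$metrics <- file.path(out, "metrics.json")
  }

  manifest <- list(
    seed = config$seed,
    stageSeeds = list(
      synth = moduleSeed(config$seed, "synth"),
      segmentation = moduleSeed(config$seed, "segmentation"),
      split = moduleSeed(config$seed, "split"),
      selection = selSeed, tuning = tuneSeed),
    nSamples = length(samples),
    trainIds = featDf$id[trainIdx], testIds = featDf$id[!trainIdx],
    timings = as.list(timings),
    artifacts = artifacts,
    configHash = sum(utf8ToInt(paste(deparse(unclass(config)),
                                     collapse = ""))))
  if (!is.null(out)) {
    jsonlite::write_json(manifest, file.path(out, "manifest.json"),
                         auto_unbox = TRUE)
  }
  list(metrics = metrics, selection = sel, svm = svmCfg, model = model,
       features = featDf, masks = masks, manifest = manifest)
}
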