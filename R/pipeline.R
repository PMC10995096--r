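#' Train a yearly quality model on raw indicator samples
#'
#' The standard training protocol of the pipeline: min-max normalize the
#' raw inputs, scale the composite-index targets onto [0.1, 0.9] for the
#' sigmoid output unit, train a plain-BP or GA-BP network, and report
#' predictions and error metrics back on the original index scale.
#'
#' @param x raw samples-by-indicators matrix (e.g. the 8 x 17 fixture).
#' @param y raw composite-index targets.
#' @param model "gabp" or "bp".
#' @param seed RNG seed for the GA and/or the random initialization.
#' @param nHidden hidden-layer size.
#' @param gaCfg,trainCfg stage configurations.
#' @return list with `predictions` (original scale), `metrics` (from
#'   [regressionMetrics()]), `net`, `errors` (BP error history),
#'   `epochs`, `converged`, and for GA-BP `gaHistory`.
#' @examples
#' \donttest{
#' s <- fixtureSamples()
#' fit <- trainYearlyModel(s$x, s$y, model = "gabp", seed = 1)
#' fit$metrics$mape
#' }
#' @export
trainYearlyModel <- function(x, y, model = c("gabp", "bp"), seed = 1,
                             nHidden = 6L, gaCfg = gaConfig(),
                             trainCfg = bpTrainConfig()) {
  model <- match.arg(model)
  stats <- minMaxFit(x)
  xs <- minMaxApply(stats, x)
  ts <- targetScale(y)
  nIn <- ncol(xs)
  fit <- if (model == "gabp")
    gaBpTrain(xs, ts$scale(y), nIn, nHidden, 1L, gaCfg = gaCfg,
              trainCfg = trainCfg, seed = seed)
  else
    bpTrain(bpInit(nIn, nHidden, 1L, seed = seed), xs, ts$scale(y),
            trainCfg)
  preds <- as.numeric(ts$invert(
    bpForward(fit$net, xs, trainCfg@outputActivation)))
  fit$predictions <- preds
  fit$metrics <- regressionMetrics(y, preds)
  fit
}

#' Assemble a pipeline run configuration
#'
#' @param source "fixtures" (the packaged study tables), "synthetic" (a
#'   generated indicator series), or "files" (user CSVs shaped like the
#'   packaged tables).
#' @param syntheticSpec for `source = "synthetic"`: a named list of
#'   arguments for [simulateIndicatorSeries()] (the seed is supplied from
#'   the master seed).
#' @param inputsPath,targetsPath for `source = "files"`: CSVs shaped like
#'   the packaged model-input and truth tables.
#' @param rasterPaths optional ASCII-grid raster files, named by year, run
#'   through [landscapeMetrics()] before modeling.
#' @param nHidden hidden-layer size.
#' @param gaCfg,trainCfg model configurations.
#' @param scale optional [LevelScale-class]; by default built from the
#'   range of the truth series.
#' @param masterSeed single seed from which every stage seed is derived.
#' @param outDir output directory (created if needed).
#' @return A `lqciRunConfig` list.
#' @export
makeRunConfig <- function(source = c("fixtures", "synthetic", "files"),
                          syntheticSpec = NULL, inputsPath = NULL,
                          targetsPath = NULL, rasterPaths = NULL,
                          nHidden = 6L, gaCfg = gaConfig(),
                          trainCfg = bpTrainConfig(), scale = NULL,
                          masterSeed = 1L, outDir = tempfile("lqci_run_")) {
  source <- match.arg(source)
  if (source == "files" && (is.null(inputsPath) || is.null(targetsPath)))
    stop("source = 'files' needs inputsPath and targetsPath")
  if (source != "synthetic" && !is.null(syntheticSpec))
    stop("syntheticSpec is only valid with source = 'synthetic'")
  structure(list(source = source, syntheticSpec = syntheticSpec,
                 inputsPath = inputsPath, targetsPath = targetsPath,
                 rasterPaths = rasterPaths, nHidden = as.integer(nHidden),
                 gaCfg = gaCfg, trainCfg = trainCfg, scale = scale,
                 masterSeed = as.integer(masterSeed), outDir = outDir),
            class = "lqciRunConfig")
}

configAsList <- function(config) {
  list(source = config$source,
       nHidden = config$nHidden,
       ga = list(populationSize = config$gaCfg@populationSize,
                 generations = config$gaCfg@generations,
                 crossoverProb = config$gaCfg@crossoverProb,
                 mutationProb = config$gaCfg@mutationProb,
                 elitismCount = config$gaCfg@elitismCount),
       train = list(learningRate = config$trainCfg@learningRate,
                    targetError = config$trainCfg@targetError,
                    maxEpochs = config$trainCfg@maxEpochs,
                    momentum = config$trainCfg@momentum,
                    outputActivation = config$trainCfg@outputActivation),
       masterSeed = config$masterSeed)
}

#' Run the full assessment pipeline
#'
#' Executes, in order: optional raster metrics, data assembly (fixtures,
#' synthetic series, or files), level assignment of the truth series,
#' plain-BP and GA-BP training, error metrics for both, leave-one-out
#' cross-validation of the GA-BP protocol, and report writing. Every
#' stage seed is derived from the master seed, so two runs with the same
#' configuration produce byte-identical reports.
#'
#' Files written to `outDir`: `report.json` (config, seed, metrics, CV),
#' `comparison.csv` (year, truth, BP and GA-BP predictions, level),
#' `ga_fitness.csv` (per-generation GA fitness), and `raster_metrics.csv`
#' when rasters are supplied.
#'
#' @param config from [makeRunConfig()].
#' @param quiet suppress per-stage messages.
#' @return Invisibly, a list with `comparison`, `metrics`, `cv`,
#'   `rasterMetrics`, `report`, `outDir`.
#' @export
runPipeline <- function(config, quiet = FALSE) {
  stopifnot(inherits(config, "lqciRunConfig"))
  say <- function(...) if (!quiet) message("[lqci] ", ...)
  dir.create(config$outDir, showWarnings = FALSE, recursive = TRUE)
  set.seed(config$masterSeed)
  seeds <- sample.int(.Machine$integer.max - 1L, 4L)  # synth, bp, gabp, cv
  say("master seed ", config$masterSeed, "; stage seeds ",
      paste(seeds, collapse = " "))

  rasterMetrics <- NULL
  if (!is.null(config$rasterPaths)) {
    say("stage raster-metrics: ", length(config$rasterPaths), " raster(s)")
    rasterMetrics <- do.call(rbind, lapply(names(config$rasterPaths),
      function(nm) {
        r <- readAsciiRaster(config$rasterPaths[[nm]])
        cbind(year = nm, landscapeMetrics(r))
      }))
    write.csv(rasterMetrics, file.path(config$outDir, "raster_metrics.csv"),
              row.names = FALSE)
  }

  say("stage data: source = ", config$source)
  if (config$source == "fixtures") {
    s <- fixtureSamples()
    years <- s$years; x <- s$x; truth <- s$y
  } else if (config$source == "synthetic") {
    spec <- config$syntheticSpec
    if (is.null(spec)) spec <- list()
    spec$seed <- seeds[1]
    sim <- do.call(simulateIndicatorSeries, spec)
    years <- sim$years; x <- sim$x; truth <- unname(sim$truth)
  } else {
    t3 <- read.csv(config$inputsPath)
    t6 <- read.csv(config$targetsPath)
    years <- t3$year
    x <- as.matrix(t3[, setdiff(names(t3), "year")])
    truth <- t6$truth_lqci
  }

  scale <- config$scale
  if (is.null(scale)) scale <- levelScale(min(truth), max(truth))
  levels <- assignLevel(truth, scale)

  say("stage train: plain BP")
  bp <- trainYearlyModel(x, truth, "bp", seed = seeds[2],
                         nHidden = config$nHidden, gaCfg = config$gaCfg,
                         trainCfg = config$trainCfg)
  say("stage train: GA-BP")
  gabp <- trainYearlyModel(x, truth, "gabp", seed = seeds[3],
                           nHidden = config$nHidden, gaCfg = config$gaCfg,
                           trainCfg = config$trainCfg)

  say("stage validate: leave-one-out over ", length(truth), " samples")
  cv <- loocv(x, truth,
              nnModelFactory("gabp", config$nHidden, config$gaCfg,
                             config$trainCfg), seed = seeds[4])

  comparison <- data.frame(year = years, truth_lqci = truth,
                           bp_pred = bp$predictions,
                           gabp_pred = gabp$predictions, level = levels)
  write.csv(comparison, file.path(config$outDir, "comparison.csv"),
            row.names = FALSE)
  write.csv(gabp$gaHistory, file.path(config$outDir, "ga_fitness.csv"),
            row.names = FALSE)

  dropDef <- function(m) m[setdiff(names(m), "mapeDefined")]
  report <- list(package = as.character(packageVersion("lqci")),
                 config = configAsList(config),
                 stageSeeds = seeds,
                 metrics = list(bp = dropDef(bp$metrics),
                                gabp = dropDef(gabp$metrics)),
                 loocv = list(cvScore = cv$cvScore,
                              perFoldMSE = cv$perFoldMSE),
                 comparison = comparison)
  jsonlite::write_json(report, file.path(config$outDir, "report.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  say("report written to ", config$outDir)
  invisible(list(comparison = comparison,
                 metrics = list(bp = bp$metrics, gabp = gabp$metrics),
                 cv = cv, rasterMetrics = rasterMetrics, report = report,
                 outDir = config$outDir))
}
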