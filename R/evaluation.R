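#' Min-max statistics fitted on training data
#'
#' `minMaxFit` records per-column minima and maxima; `minMaxApply` rescales
#' a (possibly new) matrix with those statistics, mapping constant training
#' columns to 0.5. Values outside the training range map outside [0, 1] —
#' deliberately, so held-out data are never leaked into the statistics.
#'
#' @param x training samples-by-indicators matrix.
#' @return `minMaxFit`: list with `lo`, `hi`; `minMaxApply`: rescaled
#'   matrix.
#' @export
minMaxFit <- function(x) {
  x <- rbind(x)
  list(lo = apply(x, 2, min), hi = apply(x, 2, max))
}

#' @rdname minMaxFit
#' @param stats a fit from [minMaxFit()].
#' @export
minMaxApply <- function(stats, x) {
  x <- rbind(x)
  out <- x
  for (j in seq_len(ncol(x))) {
    rng <- stats$hi[j] - stats$lo[j]
    out[, j] <- if (rng == 0) 0.5 else (x[, j] - stats$lo[j]) / rng
  }
  out
}

#' Regression error metrics
#'
#' MSE, RMSE, MAE, MAPE (percent) and the Pearson correlation r between
#' observed and predicted series. MAPE is undefined (NA, with
#' `mapeDefined = FALSE`) when any observed value is zero.
#'
#' @param yTrue,yPred equal-length numeric vectors (length >= 2).
#' @return list with `mse`, `rmse`, `mae`, `mape`, `r`, `mapeDefined`.
#' @examples
#' regressionMetrics(c(10, 20), c(11, 18))  # mae 1.5, mape 10, mse 2.5
#' @export
regressionMetrics <- function(yTrue, yPred) {
  if (length(yTrue) != length(yPred)) stop("lengths differ")
  if (length(yTrue) < 2) stop("need at least 2 observations")
  r <- yPred - yTrue
  mapeDefined <- all(yTrue != 0)
  list(mse = mean(r^2),
       rmse = sqrt(mean(r^2)),
       mae = mean(abs(r)),
       mape = if (mapeDefined) 100 * mean(abs(r) / abs(yTrue)) else NA_real_,
       r = stats::cor(yTrue, yPred),
       mapeDefined = mapeDefined)
}

#' Random 70/15/15 split
#'
#' Partitions `n` samples into train/validation/test sets of sizes
#' floor(n * p) with the remainders assigned train-first; the partition is
#' random but reproducible under `seed`, disjoint and exhaustive.
#'
#' @param n sample count (>= 3).
#' @param seed RNG seed.
#' @param props split proportions (train, validation, test).
#' @return list of index vectors `train`, `validation`, `test`.
#' @examples
#' lengths(splitTrainValTest(8, seed = 1))  # 6, 1, 1
#' @export
splitTrainValTest <- function(n, seed = 1, props = c(0.7, 0.15, 0.15)) {
  if (n < 3) stop("need at least 3 samples to split")
  stopifnot(length(props) == 3, abs(sum(props) - 1) < 1e-9)
  sizes <- floor(n * props)
  rem <- n - sum(sizes)
  if (rem > 0)  # leftover samples go to train, then validation, then test
    sizes[seq_len(rem)] <- sizes[seq_len(rem)] + 1L
  set.seed(seed)
  idx <- sample.int(n)
  list(train = sort(idx[seq_len(sizes[1])]),
       validation = sort(idx[sizes[1] + seq_len(sizes[2])]),
       test = sort(idx[sizes[1] + sizes[2] + seq_len(sizes[3])]))
}

#' Leave-one-out cross-validation
#'
#' For each sample i, `trainFun` is fitted on all other samples (with a
#' fold seed derived reproducibly from the master seed) and used to
#' predict sample i; MSE_i is the squared error of that single prediction
#' and the CV score is their mean. Any preprocessing (normalization,
#' target scaling) must live inside `trainFun` so it is fitted on the
#' training fold only. A failing fold is dropped with a warning and the
#' score is reported over the completed folds.
#'
#' @param x samples-by-inputs matrix of raw inputs.
#' @param y raw targets.
#' @param trainFun function(xTrain, yTrain, seed) returning a prediction
#'   function(xNew) on the original target scale.
#' @param seed master seed for the per-fold seeds.
#' @return list with `perFoldMSE`, `cvScore` (mean of the completed
#'   folds), `nFolds`, `predictions`, `failedFolds`.
#' @export
loocv <- function(x, y, trainFun, seed = 1) {
  x <- rbind(x)
  n <- nrow(x)
  if (n < 2) stop("need at least 2 samples for leave-one-out")
  set.seed(seed)
  foldSeeds <- sample.int(.Machine$integer.max - 1L, n)
  perFold <- rep(NA_real_, n)
  preds <- rep(NA_real_, n)
  failed <- integer(0)
  for (i in seq_len(n)) {
    res <- tryCatch({
      predict_i <- trainFun(x[-i, , drop = FALSE], y[-i], foldSeeds[i])
      as.numeric(predict_i(x[i, , drop = FALSE]))
    }, error = function(e) {
      warning("fold ", i, " failed: ", conditionMessage(e))
      NULL
    })
    if (is.null(res)) failed <- c(failed, i)
    else {
      preds[i] <- res
      perFold[i] <- (res - y[i])^2
    }
  }
  list(perFoldMSE = perFold, cvScore = mean(perFold, na.rm = TRUE),
       nFolds = n, predictions = preds, failedFolds = failed)
}

#' Neural-network model factory for cross-validation
#'
#' Builds the `trainFun` that [loocv()] expects: inside each fold it fits
#' min-max input normalization and the [0.1, 0.9] target scaling on the
#' training fold only, trains a plain-BP or GA-BP network, and returns a
#' predictor reporting on the original target scale.
#'
#' @param model "gabp" or "bp".
#' @param nHidden hidden layer size.
#' @param gaCfg,trainCfg configurations for the two training stages.
#' @return function(xTrain, yTrain, seed) -> function(xNew).
#' @export
nnModelFactory <- function(model = c("gabp", "bp"), nHidden = 6L,
                           gaCfg = gaConfig(), trainCfg = bpTrainConfig()) {
  model <- match.arg(model)
  function(xTrain, yTrain, seed) {
    stats <- minMaxFit(xTrain)
    xs <- minMaxApply(stats, xTrain)
    ts <- targetScale(yTrain)
    nIn <- ncol(xs)
    fit <- if (model == "gabp")
      gaBpTrain(xs, ts$scale(yTrain), nIn, nHidden, 1L, gaCfg = gaCfg,
                trainCfg = trainCfg, seed = seed)
    else
      bpTrain(bpInit(nIn, nHidden, 1L, seed = seed), xs, ts$scale(yTrain),
              trainCfg)
    function(xNew) ts$invert(bpForward(fit$net, minMaxApply(stats, xNew),
                                       trainCfg@outputActivation))
  }
}
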