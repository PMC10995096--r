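#' @import methods
#' @importFrom stats runif rnorm sd median quantile cor coef lm setNames
#' @importFrom utils read.csv write.csv packageVersion
NULL

#' Categorical land-cover raster
#'
#' A single-band integer grid of land-cover class labels on a square-cell
#' lattice. Class labels are non-negative integers; one reserved label marks
#' nodata cells. The cell edge length is carried in meters so that patch
#' areas and densities can be reported in hectares and square kilometers.
#'
#' @slot grid integer matrix of class labels (rows x cols).
#' @slot cellSize cell edge length in meters (> 0).
#' @slot nodata reserved label for cells outside the landscape.
#'
#' @seealso [categoricalRaster()], [labelPatches()], [classMetrics()]
#' @export
setClass("CategoricalRaster",
  representation(grid = "matrix", cellSize = "numeric", nodata = "integer"),
  prototype(cellSize = 1, nodata = -1L))

setValidity("CategoricalRaster", function(object) {
  msg <- NULL
  g <- object@grid
  if (!is.numeric(g)) msg <- c(msg, "grid must be a numeric/integer matrix")
  if (length(object@cellSize) != 1L || is.na(object@cellSize) ||
      object@cellSize <= 0)
    msg <- c(msg, "cellSize must be a single positive number")
  if (is.numeric(g)) {
    vals <- g[!is.na(g)]
    if (any(vals != floor(vals))) msg <- c(msg, "grid labels must be integers")
    if (any(vals < 0 & vals != object@nodata))
      msg <- c(msg, "grid labels must be >= 0 (or the nodata label)")
  }
  if (is.null(msg)) TRUE else msg
})

#' Construct a CategoricalRaster
#'
#' @param grid integer matrix of class labels.
#' @param cellSize cell edge length in meters.
#' @param nodata reserved nodata label (default -1).
#' @return A [CategoricalRaster-class] object.
#' @examples
#' r <- categoricalRaster(matrix(c(0, 1, 1, 0), 2, 2), cellSize = 100)
#' @export
categoricalRaster <- function(grid, cellSize = 1, nodata = -1L) {
  storage.mode(grid) <- "integer"
  new("CategoricalRaster", grid = grid, cellSize = as.numeric(cellSize),
      nodata = as.integer(nodata))
}

#' The patches of one class in a raster
#'
#' Maximal connected components of the cells carrying one class label,
#' under 4- or 8-neighbor connectivity. The `labels` matrix assigns 0 to
#' cells of other classes and 1..nPatches to the component each class cell
#' belongs to.
#'
#' @slot classLabel the class whose patches are delineated.
#' @slot connectivity 4 or 8.
#' @slot labels integer matrix of patch memberships.
#' @slot nPatches number of patches found.
#' @export
setClass("PatchSet",
  representation(classLabel = "integer", connectivity = "integer",
                 labels = "matrix", nPatches = "integer"))

setValidity("PatchSet", function(object) {
  msg <- NULL
  if (!object@connectivity %in% c(4L, 8L))
    msg <- c(msg, "connectivity must be 4 or 8")
  k <- object@nPatches
  lab <- object@labels
  if (k > 0 && !setequal(unique(lab[lab > 0]), seq_len(k)))
    msg <- c(msg, "labels must use ids 1..nPatches")
  if (k == 0 && any(lab > 0))
    msg <- c(msg, "nPatches is 0 but labels contains patch cells")
  if (is.null(msg)) TRUE else msg
})

#' Weighted indicator system for the composite landscape quality index
#'
#' Holds the evaluation indicators with their criterion-layer membership
#' (socio-economic SEI, ecological-environment EEI, landscape-pattern LPCI),
#' AHP-derived weights in percent, and polarity (benefit indicators raise
#' quality as they grow, cost indicators lower it).
#'
#' @slot table data.frame with columns id, abbrev, name, layer, class,
#'   weight_percent, polarity.
#' @export
setClass("IndicatorSystem", representation(table = "data.frame"))

setValidity("IndicatorSystem", function(object) {
  tb <- object@table
  need <- c("id", "abbrev", "layer", "weight_percent", "polarity")
  msg <- NULL
  if (!all(need %in% names(tb)))
    msg <- c(msg, paste("missing columns:",
                        paste(setdiff(need, names(tb)), collapse = ", ")))
  else {
    if (anyDuplicated(tb$id)) msg <- c(msg, "indicator ids must be unique")
    if (any(!is.finite(tb$weight_percent)) || any(tb$weight_percent <= 0))
      msg <- c(msg, "weights must be finite and > 0")
    if (!all(tb$polarity %in% c("benefit", "cost")))
      msg <- c(msg, "polarity must be 'benefit' or 'cost'")
  }
  if (is.null(msg)) TRUE else msg
})

#' @rdname IndicatorSystem-class
#' @param table data.frame of indicator definitions.
#' @export
indicatorSystem <- function(table) new("IndicatorSystem", table = table)

#' Ordinal level scale for composite index scores
#'
#' Maps a composite score x onto one of `nLevels` ordered quality levels by
#' k = ceiling((x - s1) / (sn - s1) * nLevels), clamped to 1..nLevels.
#' Labels are ordered best-first (I is best), and the top ordinal k maps to
#' the best label.
#'
#' @slot s1 lowest score of the scale.
#' @slot sn highest score of the scale.
#' @slot nLevels number of levels.
#' @slot labels level labels ordered best-first.
#' @export
setClass("LevelScale",
  representation(s1 = "numeric", sn = "numeric", nLevels = "integer",
                 labels = "character"))

setValidity("LevelScale", function(object) {
  msg <- NULL
  if (object@sn <= object@s1) msg <- c(msg, "sn must exceed s1")
  if (object@nLevels < 2L) msg <- c(msg, "need at least 2 levels")
  if (length(object@labels) != object@nLevels)
    msg <- c(msg, "labels length must equal nLevels")
  if (is.null(msg)) TRUE else msg
})

#' @rdname LevelScale-class
#' @param s1,sn lowest and highest scores.
#' @param nLevels number of levels.
#' @param labels labels, best first.
#' @examples
#' levelScale(28.77, 43.72)
#' @export
levelScale <- function(s1, sn, nLevels = 4L,
                       labels = c("I", "II", "III", "IV")) {
  new("LevelScale", s1 = as.numeric(s1), sn = as.numeric(sn),
      nLevels = as.integer(nLevels), labels = labels)
}

#' One-hidden-layer feed-forward network parameters
#'
#' The weight/bias set of a network with sigmoid hidden units:
#' `u = sigmoid(v1 x + b1)`, `yhat = act(w2 u + b2)` where `act` is either
#' the sigmoid or the identity.
#'
#' @slot v1 input-to-hidden weight matrix (nHidden x nIn).
#' @slot b1 hidden biases (length nHidden).
#' @slot w2 hidden-to-output weight matrix (nOut x nHidden).
#' @slot b2 output biases (length nOut).
#' @export
setClass("BPNetwork",
  representation(v1 = "matrix", b1 = "numeric", w2 = "matrix",
                 b2 = "numeric"))

setValidity("BPNetwork", function(object) {
  msg <- NULL
  if (nrow(object@v1) != length(object@b1))
    msg <- c(msg, "nrow(v1) must equal length(b1)")
  if (ncol(object@w2) != nrow(object@v1))
    msg <- c(msg, "ncol(w2) must equal nrow(v1)")
  if (nrow(object@w2) != length(object@b2))
    msg <- c(msg, "nrow(w2) must equal length(b2)")
  if (!all(is.finite(object@v1)) || !all(is.finite(object@b1)) ||
      !all(is.finite(object@w2)) || !all(is.finite(object@b2)))
    msg <- c(msg, "all parameters must be finite")
  if (is.null(msg)) TRUE else msg
})

#' Backpropagation training configuration
#'
#' @slot learningRate gradient-descent step size.
#' @slot targetError early-stop threshold R on the half-sum-of-squares
#'   error E; training stops as soon as E < R.
#' @slot maxEpochs iteration cap.
#' @slot momentum classical momentum coefficient in [0, 1).
#' @slot outputActivation "sigmoid" or "linear".
#' @export
setClass("BPTrainConfig",
  representation(learningRate = "numeric", targetError = "numeric",
                 maxEpochs = "integer", momentum = "numeric",
                 outputActivation = "character"),
  prototype(learningRate = 0.001, targetError = 0.001, maxEpochs = 50000L,
            momentum = 0.9, outputActivation = "sigmoid"))

setValidity("BPTrainConfig", function(object) {
  msg <- NULL
  if (object@learningRate <= 0) msg <- c(msg, "learningRate must be > 0")
  if (object@targetError <= 0) msg <- c(msg, "targetError must be > 0")
  if (object@maxEpochs < 1L) msg <- c(msg, "maxEpochs must be >= 1")
  if (object@momentum < 0 || object@momentum >= 1)
    msg <- c(msg, "momentum must be in [0, 1)")
  if (!object@outputActivation %in% c("sigmoid", "linear"))
    msg <- c(msg, "outputActivation must be 'sigmoid' or 'linear'")
  if (is.null(msg)) TRUE else msg
})

#' @rdname BPTrainConfig-class
#' @param learningRate,targetError,maxEpochs,momentum,outputActivation
#'   see slots.
#' @export
bpTrainConfig <- function(learningRate = 0.001, targetError = 0.001,
                          maxEpochs = 50000L, momentum = 0.9,
                          outputActivation = c("sigmoid", "linear")) {
  new("BPTrainConfig", learningRate = learningRate,
      targetError = targetError, maxEpochs = as.integer(maxEpochs),
      momentum = momentum,
      outputActivation = match.arg(outputActivation))
}

#' Genetic algorithm configuration
#'
#' Defaults follow the study conditions: population size 20, 100
#' generations, crossover probability 0.3, mutation probability 0.1, and
#' one elite chromosome carried over unchanged each generation.
#'
#' @slot populationSize number of chromosomes N.
#' @slot generations number of generations.
#' @slot crossoverProb per-pair arithmetic crossover probability Pe.
#' @slot mutationProb per-gene mutation probability Pm.
#' @slot elitismCount elites copied unchanged into the next generation.
#' @export
setClass("GAConfig",
  representation(populationSize = "integer", generations = "integer",
                 crossoverProb = "numeric", mutationProb = "numeric",
                 elitismCount = "integer"),
  prototype(populationSize = 20L, generations = 100L, crossoverProb = 0.3,
            mutationProb = 0.1, elitismCount = 1L))

setValidity("GAConfig", function(object) {
  msg <- NULL
  if (object@populationSize < 2L) msg <- c(msg, "populationSize must be >= 2")
  if (object@generations < 0L) msg <- c(msg, "generations must be >= 0")
  if (object@crossoverProb < 0 || object@crossoverProb > 1)
    msg <- c(msg, "crossoverProb must be in [0, 1]")
  if (object@mutationProb < 0 || object@mutationProb > 1)
    msg <- c(msg, "mutationProb must be in [0, 1]")
  if (object@elitismCount < 0L || object@elitismCount >= object@populationSize)
    msg <- c(msg, "elitismCount must be in [0, populationSize)")
  if (is.null(msg)) TRUE else msg
})

#' @rdname GAConfig-class
#' @param populationSize,generations,crossoverProb,mutationProb,elitismCount
#'   see slots.
#' @export
gaConfig <- function(populationSize = 20L, generations = 100L,
                     crossoverProb = 0.3, mutationProb = 0.1,
                     elitismCount = 1L) {
  new("GAConfig", populationSize = as.integer(populationSize),
      generations = as.integer(generations), crossoverProb = crossoverProb,
      mutationProb = mutationProb, elitismCount = as.integer(elitismCount))
}
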