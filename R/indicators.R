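#' @importFrom SummarizedExperiment SummarizedExperiment assay assay<-
#'   assayNames rowData colData
#' @importClassesFrom SummarizedExperiment SummarizedExperiment
#' @importFrom S4Vectors DataFrame metadata metadata<-
NULL

## ---- min-max normalization ------------------------------------------------

minMaxColumn <- function(x, polarity = "benefit") {
  fin <- is.finite(x)
  if (!any(fin)) stop("indicator column has no finite values")
  lo <- min(x[fin]); hi <- max(x[fin])
  if (hi == lo) {
    out <- rep(0.5, length(x))
    attr(out, "constant") <- TRUE
    return(out)
  }
  v <- (x - lo) / (hi - lo)
  if (polarity == "cost") v <- 1 - v
  v
}

#' @describeIn normalizeIndicators years-by-indicators matrix; `polarity`
#'   is recycled across columns.
#' @param polarity "benefit" or "cost", per indicator column.
#' @export
setMethod("normalizeIndicators", "matrix", function(x, polarity = "benefit",
                                                    ...) {
  polarity <- rep_len(polarity, ncol(x))
  out <- x
  const <- logical(ncol(x))
  for (j in seq_len(ncol(x))) {
    v <- minMaxColumn(x[, j], polarity[j])
    const[j] <- isTRUE(attr(v, "constant"))
    out[, j] <- v
  }
  attr(out, "constant") <- const
  out
})

#' @describeIn normalizeIndicators adds a `"normalized"` assay computed
#'   from the `"raw"` assay using `rowData(x)$polarity`.
#' @export
setMethod("normalizeIndicators", "SummarizedExperiment", function(x, ...) {
  raw <- assay(x, "raw")
  pol <- rowData(x)$polarity
  if (is.null(pol)) pol <- "benefit"
  norm <- t(normalizeIndicators(t(raw), polarity = pol))
  assay(x, "normalized") <- norm
  x
})

## ---- the composite index --------------------------------------------------

#' @describeIn computeLQCI one year's normalized indicator vector.
#' @export
setMethod("computeLQCI", c("numeric", "numeric"), function(x, weights, ...) {
  if (length(x) != length(weights))
    stop("normalized values and weights must have equal length")
  if (any(x < -1e-9 | x > 1 + 1e-9, na.rm = TRUE))
    stop("normalized values must lie in [0, 1]")
  sum(weights * x)
})

#' @describeIn computeLQCI years-by-indicators normalized matrix; returns
#'   one score per row (year).
#' @export
setMethod("computeLQCI", c("matrix", "numeric"), function(x, weights, ...) {
  if (ncol(x) != length(weights))
    stop("ncol(x) must equal length(weights)")
  apply(x, 1L, function(v) computeLQCI(v, weights))
})

#' @describeIn computeLQCI uses the `"normalized"` assay (computing it if
#'   absent) and `rowData(x)$weight_percent`.
#' @export
setMethod("computeLQCI", c("SummarizedExperiment", "missing"),
          function(x, weights, ...) {
  if (!"normalized" %in% assayNames(x)) x <- normalizeIndicators(x)
  w <- rowData(x)$weight_percent
  if (is.null(w)) stop("rowData(x) must carry a 'weight_percent' column")
  computeLQCI(t(assay(x, "normalized")), as.numeric(w))
})

#' Assemble a year-by-indicator experiment
#'
#' Packs a years-by-indicators raw value matrix into a
#' `SummarizedExperiment` (indicators as rows, years as columns) with the
#' indicator system in the rowData, the container the rest of the indicator
#' pipeline operates on.
#'
#' @param values years-by-indicators numeric matrix.
#' @param indicators an [IndicatorSystem-class] (or data.frame) aligned
#'   with the columns of `values`.
#' @param years calendar years, defaults to the rownames of `values`.
#' @return A `SummarizedExperiment` with a `"raw"` assay.
#' @export
indicatorExperiment <- function(values, indicators, years = NULL) {
  if (is(indicators, "IndicatorSystem")) indicators <- indicators@table
  stopifnot(ncol(values) == nrow(indicators))
  if (is.null(years)) years <- rownames(values)
  if (is.null(years)) years <- seq_len(nrow(values))
  se <- SummarizedExperiment(
    assays = list(raw = t(values)),
    rowData = DataFrame(indicators),
    colData = DataFrame(year = as.integer(years)))
  colnames(se) <- as.character(years)
  se
}

## ---- level assignment -----------------------------------------------------

#' Assign ordinal quality levels to composite scores
#'
#' Computes k = ceiling((x - s1) / (sn - s1) * nLevels), clamps k to
#' 1..nLevels, and maps the highest ordinal to the best label (level I).
#' Scores at s1 therefore fall in the worst level and scores at sn in the
#' best.
#'
#' @param x numeric composite score(s); must be finite.
#' @param scale a [LevelScale-class].
#' @return Character vector of level labels.
#' @examples
#' assignLevel(c(28.77, 40.27, 43.72), levelScale(28.77, 43.72))
#' @export
assignLevel <- function(x, scale) {
  stopifnot(is(scale, "LevelScale"))
  if (any(!is.finite(x))) stop("scores must be finite")
  n <- scale@nLevels
  k <- ceiling((x - scale@s1) / (scale@sn - scale@s1) * n)
  k <- pmin(pmax(k, 1L), n)
  scale@labels[n - k + 1L]
}

## ---- AHP ------------------------------------------------------------------

# Saaty's random consistency index by matrix order.
AHP_RANDOM_INDEX <- c(0, 0, 0.58, 0.90, 1.12, 1.24, 1.32, 1.41, 1.45, 1.49,
                      1.51, 1.54, 1.56, 1.57, 1.59)

#' AHP weights from a pairwise comparison matrix
#'
#' Derives criterion weights as the normalized principal eigenvector of a
#' positive reciprocal pairwise comparison matrix, with Saaty's consistency
#' ratio CR = ((lambda_max - n) / (n - 1)) / RI(n). Comparisons with
#' CR below `crThreshold` are conventionally considered consistent.
#'
#' @param pairwise n x n positive reciprocal matrix (a_ji = 1 / a_ij,
#'   unit diagonal).
#' @param crThreshold acceptance threshold on CR (default 0.1).
#' @return list with `weights` (summing to 1), `lambdaMax`,
#'   `consistencyRatio`, and `consistent`.
#' @examples
#' P <- matrix(c(1, 2, 4, 1/2, 1, 2, 1/4, 1/2, 1), 3, 3, byrow = TRUE)
#' ahpWeights(P)
#' @export
ahpWeights <- function(pairwise, crThreshold = 0.1) {
  n <- nrow(pairwise)
  if (is.null(n) || n < 2L || n != ncol(pairwise))
    stop("pairwise must be a square matrix of order >= 2")
  if (any(pairwise <= 0)) stop("pairwise entries must be positive")
  if (max(abs(pairwise * t(pairwise) - 1)) > 1e-8)
    stop("pairwise must be reciprocal (a_ji = 1/a_ij with unit diagonal)")
  eig <- eigen(pairwise)
  i <- which.max(Re(eig$values))
  lambda <- Re(eig$values[i])
  w <- Re(eig$vectors[, i])
  w <- w / sum(w)
  ci <- (lambda - n) / (n - 1)
  ri <- if (n <= length(AHP_RANDOM_INDEX)) AHP_RANDOM_INDEX[n] else 1.59
  cr <- if (ri == 0) 0 else ci / ri
  list(weights = w, lambdaMax = lambda, consistencyRatio = cr,
       consistent = cr <= crThreshold)
}

## ---- accessors / show -----------------------------------------------------

#' @describeIn IndicatorSystem-class weights in percent, in indicator order.
#' @export
setMethod("indicatorWeights", "IndicatorSystem",
          function(x) setNames(x@table$weight_percent, x@table$abbrev))

#' @export
setMethod("show", "IndicatorSystem", function(object) {
  tb <- object@table
  cat("IndicatorSystem with", nrow(tb), "indicators\n")
  for (ly in unique(tb$layer)) {
    w <- sum(tb$weight_percent[tb$layer == ly])
    cat(sprintf("  %-5s %2d indicators, total weight %6.3f%%\n",
                ly, sum(tb$layer == ly), w))
  }
  cat(sprintf("  total weight %.3f%%\n", sum(tb$weight_percent)))
})

#' @export
setMethod("show", "LevelScale", function(object) {
  cat(sprintf("LevelScale [%g, %g] with %d levels (%s best-first)\n",
              object@s1, object@sn, object@nLevels,
              paste(object@labels, collapse = " > ")))
})
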