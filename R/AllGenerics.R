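#' Number of patches in a PatchSet
#' @param x a [PatchSet-class].
#' @export
setGeneric("nPatches", function(x) standardGeneric("nPatches"))

#' Cell size accessor
#' @param x a [CategoricalRaster-class].
#' @export
setGeneric("cellSize", function(x) standardGeneric("cellSize"))

#' Raster grid accessor
#' @param x a [CategoricalRaster-class] or [PatchSet-class].
#' @export
setGeneric("rasterGrid", function(x) standardGeneric("rasterGrid"))

#' Min-max normalize indicator values to [0, 1]
#'
#' Benefit indicators map as (x - min) / (max - min), cost indicators as
#' (max - x) / (max - min). A constant column maps to 0.5 everywhere and is
#' flagged in the `"constant"` attribute.
#'
#' @param x a years-by-indicators numeric matrix, or a
#'   `SummarizedExperiment` whose `"raw"` assay is indicators-by-years with
#'   a `polarity` column in its rowData.
#' @param ... passed on to methods.
#' @return Same shape as the input; for a `SummarizedExperiment`, the
#'   object with a new `"normalized"` assay.
#' @export
setGeneric("normalizeIndicators",
           function(x, ...) standardGeneric("normalizeIndicators"))

#' Landscape Quality Composite Index
#'
#' LQCI = sum_j w_j * V_ij with weights w_j in percent and V the min-max
#' normalized indicator values, so a year scoring 1 on every indicator
#' attains sum(w).
#'
#' @param x normalized indicator values: a numeric vector (one year), a
#'   years-by-indicators matrix, or a `SummarizedExperiment` carrying a
#'   `"normalized"` assay and per-indicator weights in rowData.
#' @param weights indicator weights in percent, aligned with the indicator
#'   order of `x` (ignored for `SummarizedExperiment`, which carries them).
#' @param ... passed on to methods.
#' @return Numeric LQCI score(s), one per year.
#' @export
setGeneric("computeLQCI", function(x, weights, ...)
  standardGeneric("computeLQCI"))

#' Indicator weights accessor
#' @param x an [IndicatorSystem-class].
#' @export
setGeneric("indicatorWeights", function(x) standardGeneric("indicatorWeights"))
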