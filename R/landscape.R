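#' @useDynLib lqci, .registration = TRUE
#' @importFrom Rcpp sourceCpp
NULL

#' Delineate the patches of one class
#'
#' Labels the maximal connected components of the cells carrying
#' `classLabel`, under 8-neighbor (default, the usual raster-ecology
#' convention) or 4-neighbor connectivity. A class absent from the raster
#' yields an empty patch set.
#'
#' @param raster a [CategoricalRaster-class].
#' @param classLabel the class to delineate.
#' @param connectivity 4 or 8.
#' @return A [PatchSet-class].
#' @examples
#' r <- categoricalRaster(rbind(c(1, 0), c(0, 1)))
#' nPatches(labelPatches(r, 1, connectivity = 8))  # 1: diagonal touch
#' nPatches(labelPatches(r, 1, connectivity = 4))  # 2
#' @export
labelPatches <- function(raster, classLabel, connectivity = 8) {
  stopifnot(is(raster, "CategoricalRaster"))
  connectivity <- as.integer(connectivity)
  if (!connectivity %in% c(4L, 8L)) stop("connectivity must be 4 or 8")
  lab <- cpp_label_patches(raster@grid, as.integer(classLabel), connectivity)
  new("PatchSet", classLabel = as.integer(classLabel),
      connectivity = connectivity, labels = lab,
      nPatches = max(0L, max(lab)))
}

# like adjacencies of a logical mask: 4-neighbor cell pairs, counted once
likeAdjacencies <- function(mask) {
  h <- if (ncol(mask) > 1) sum(mask[, -ncol(mask)] & mask[, -1]) else 0L
  v <- if (nrow(mask) > 1) sum(mask[-nrow(mask), ] & mask[-1, ]) else 0L
  h + v
}

# maximum possible like adjacencies for A cells: largest-integer-square
# construction n = floor(sqrt(A)) with the standard remainder correction
maxLikeAdjacencies <- function(A) {
  n <- floor(sqrt(A))
  m <- A - n^2
  if (m == 0) 2 * n * (n - 1)
  else if (m <= n) 2 * n * (n - 1) + 2 * m - 1
  else 2 * n * (n - 1) + 2 * m - 2
}

#' Class-level landscape pattern metrics
#'
#' Computes the six class-level metrics of the quality-assessment pipeline
#' from a categorical raster, using the standard raster (FRAGSTATS-style)
#' definitions:
#' \describe{
#'   \item{np}{number of patches (connected components).}
#'   \item{pd}{patch density, NP per square kilometer of landscape.}
#'   \item{area_mn}{mean patch area in hectares.}
#'   \item{lpi}{largest patch index, percent of the landscape occupied by
#'     the largest patch.}
#'   \item{lsi}{landscape shape index, 0.25 E / sqrt(A) with E the total
#'     class edge length in cell edges (landscape boundary included) and A
#'     the class area in cells; 1 for a maximally compact square class.}
#'   \item{ai}{aggregation index, 100 g / g_max where g counts 4-neighbor
#'     like adjacencies once and g_max is the maximum attainable for the
#'     class area; undefined (NA) for classes of a single cell.}
#' }
#' An empty class reports np = 0, pd = 0 and NA for the remaining metrics.
#'
#' @inheritParams labelPatches
#' @param patches optionally, a precomputed [PatchSet-class] for the class.
#' @return A one-row data.frame with columns np, pd, area_mn, lpi, lsi, ai.
#' @examples
#' g <- matrix(0L, 10, 10); g[2:3, 2:3] <- 1L
#' classMetrics(categoricalRaster(g, cellSize = 100), 1)
#' @export
classMetrics <- function(raster, classLabel, connectivity = 8,
                         patches = NULL) {
  stopifnot(is(raster, "CategoricalRaster"))
  if (is.null(patches))
    patches <- labelPatches(raster, classLabel, connectivity)
  stopifnot(is(patches, "PatchSet"),
            patches@classLabel == as.integer(classLabel))
  grid <- raster@grid
  landCells <- sum(grid != raster@nodata & !is.na(grid))
  if (landCells < 1) stop("raster has no non-nodata cells")
  cellHa <- raster@cellSize^2 / 1e4
  landKm2 <- landCells * raster@cellSize^2 / 1e6

  np <- patches@nPatches
  if (np == 0)
    return(data.frame(np = 0L, pd = 0, area_mn = NA_real_, lpi = NA_real_,
                      lsi = NA_real_, ai = NA_real_))
  sizes <- tabulate(patches@labels[patches@labels > 0], nbins = np)
  A <- sum(sizes)
  mask <- !is.na(grid) & grid == as.integer(classLabel)
  g <- likeAdjacencies(mask)
  edge <- 4 * A - 2 * g
  gmax <- maxLikeAdjacencies(A)
  data.frame(
    np = np,
    pd = np / landKm2,
    area_mn = mean(sizes) * cellHa,
    lpi = 100 * max(sizes) / landCells,
    lsi = 0.25 * edge / sqrt(A),
    ai = if (gmax > 0) 100 * g / gmax else NA_real_)
}

#' Metrics for every class of a raster
#'
#' @inheritParams classMetrics
#' @param classes class labels to report; defaults to every non-nodata
#'   label present.
#' @return data.frame with one row per class, columns class, np, pd,
#'   area_mn, lpi, lsi, ai.
#' @export
landscapeMetrics <- function(raster, classes = NULL, connectivity = 8) {
  stopifnot(is(raster, "CategoricalRaster"))
  if (is.null(classes)) {
    classes <- sort(unique(as.vector(raster@grid)))
    classes <- classes[!is.na(classes) & classes != raster@nodata]
  }
  out <- do.call(rbind, lapply(classes, function(cl)
    cbind(class = cl, classMetrics(raster, cl, connectivity))))
  rownames(out) <- NULL
  out
}

## ---- accessors, show, text I/O -------------------------------------------

#' @describeIn CategoricalRaster-class cell edge length in meters.
#' @export
setMethod("cellSize", "CategoricalRaster", function(x) x@cellSize)

#' @describeIn CategoricalRaster-class the label matrix.
#' @export
setMethod("rasterGrid", "CategoricalRaster", function(x) x@grid)

#' @describeIn PatchSet-class patch count.
#' @export
setMethod("nPatches", "PatchSet", function(x) x@nPatches)

#' @describeIn PatchSet-class the patch-id matrix (0 = other classes).
#' @export
setMethod("rasterGrid", "PatchSet", function(x) x@labels)

#' @export
setMethod("show", "CategoricalRaster", function(object) {
  g <- object@grid
  cls <- sort(unique(as.vector(g)))
  cls <- cls[!is.na(cls) & cls != object@nodata]
  cat(sprintf("CategoricalRaster %d x %d, cell %g m, classes: %s\n",
              nrow(g), ncol(g), object@cellSize,
              paste(cls, collapse = " ")))
})

#' @export
setMethod("show", "PatchSet", function(object) {
  cat(sprintf("PatchSet: class %d, %d patch(es), %d-connectivity\n",
              object@classLabel, object@nPatches, object@connectivity))
})

#' Read / write a raster as a plain ASCII grid
#'
#' The text format is a 2-line header (`cellsize <m>` and `nodata <label>`)
#' followed by the whitespace-delimited label matrix, one raster row per
#' line.
#'
#' @param raster a [CategoricalRaster-class].
#' @param path file path.
#' @return `readAsciiRaster` returns a [CategoricalRaster-class];
#'   `writeAsciiRaster` returns `path` invisibly.
#' @export
writeAsciiRaster <- function(raster, path) {
  stopifnot(is(raster, "CategoricalRaster"))
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c(paste("cellsize", format(raster@cellSize)),
               paste("nodata", raster@nodata)), con)
  write.table(raster@grid, con, row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' @rdname writeAsciiRaster
#' @export
readAsciiRaster <- function(path) {
  hdr <- readLines(path, n = 2L)
  cs <- as.numeric(strsplit(hdr[1], "\\s+")[[1]][2])
  nd <- as.integer(strsplit(hdr[2], "\\s+")[[1]][2])
  grid <- as.matrix(read.table(path, skip = 2L))
  dimnames(grid) <- NULL
  categoricalRaster(grid, cellSize = cs, nodata = nd)
}
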