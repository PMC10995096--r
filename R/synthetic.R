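#' Simulate yearly indicator series with a known-weight composite target
#'
#' Generates a years-by-indicators raw matrix as independent linear trends
#' plus Gaussian noise, then derives the true composite series through the
#' same min-max normalization and weighted-sum pathway the real pipeline
#' uses, so the generating weights are exact ground truth for downstream
#' tests. Deterministic under `seed`.
#'
#' Defaults emulate the study conditions: 8 yearly records starting 2015
#' and, for 29 indicators, the packaged indicator-system weights.
#'
#' @param nYears number of years (>= 3).
#' @param nIndicators number of indicators.
#' @param trendSlopes per-indicator drift per year; default drawn once from
#'   N(2, 1) under `seed`.
#' @param noiseSd per-indicator noise SD (>= 0); default 5 percent of each
#'   indicator's trend range.
#' @param trueWeights per-indicator weights in percent; default the
#'   packaged 29-indicator weights when `nIndicators` is 29, otherwise
#'   equal weights summing to 100.
#' @param baseLevels per-indicator level in year 1; default drawn once from
#'   U(10, 100).
#' @param startYear first calendar year.
#' @param seed RNG seed.
#' @return list with `x` (raw years-by-indicators matrix), `normalized`,
#'   `truth` (composite series), `weights`, `years`, and `experiment` (a
#'   `SummarizedExperiment` holding both assays).
#' @examples
#' sim <- simulateIndicatorSeries(nYears = 5, nIndicators = 3,
#'                                trueWeights = c(10, 20, 30),
#'                                noiseSd = 0, seed = 1)
#' sim$truth
#' @export
simulateIndicatorSeries <- function(nYears = 8, nIndicators = 29,
                                    trendSlopes = NULL, noiseSd = NULL,
                                    trueWeights = NULL, baseLevels = NULL,
                                    startYear = 2015, seed = 1) {
  if (nYears < 3) stop("nYears must be >= 3")
  set.seed(seed)
  if (is.null(trendSlopes)) trendSlopes <- rnorm(nIndicators, 2, 1)
  trendSlopes <- rep_len(trendSlopes, nIndicators)
  if (is.null(baseLevels)) baseLevels <- runif(nIndicators, 10, 100)
  baseLevels <- rep_len(baseLevels, nIndicators)
  if (is.null(noiseSd)) noiseSd <- 0.05 * abs(trendSlopes) * (nYears - 1)
  noiseSd <- rep_len(noiseSd, nIndicators)
  if (any(noiseSd < 0)) stop("noiseSd must be >= 0")
  if (is.null(trueWeights)) {
    trueWeights <- if (nIndicators == 29)
      unname(indicatorWeights(loadFixture("table2")))
    else rep(100 / nIndicators, nIndicators)
  }
  if (length(trueWeights) != nIndicators)
    stop("trueWeights must have length nIndicators")

  years <- seq(startYear, length.out = nYears)
  x <- sapply(seq_len(nIndicators), function(j)
    baseLevels[j] + trendSlopes[j] * (seq_len(nYears) - 1) +
      rnorm(nYears, 0, noiseSd[j]))
  dimnames(x) <- list(years, sprintf("V%02d", seq_len(nIndicators)))
  norm <- normalizeIndicators(x)
  truth <- computeLQCI(norm, trueWeights)
  ind <- data.frame(id = seq_len(nIndicators), abbrev = colnames(x),
                    name = colnames(x), layer = "SYN", class = "",
                    weight_percent = trueWeights, polarity = "benefit")
  se <- indicatorExperiment(x, indicatorSystem(ind), years = years)
  SummarizedExperiment::assay(se, "normalized") <- t(norm)
  S4Vectors::metadata(se)$truth <- truth
  list(x = x, normalized = norm, truth = truth, weights = trueWeights,
       years = years, experiment = se)
}

# free cell valid for the growing patch: not occupied, and not 8-adjacent
# to a same-class cell of a *different* patch (keeps requested patches from
# merging, so the generator's patch count is exact ground truth)
.validCell <- function(i, j, grid, patchIds, cls, patch) {
  nr <- nrow(grid); nc <- ncol(grid)
  if (grid[i, j] != 0L) return(FALSE)
  for (di in -1:1) for (dj in -1:1) {
    ii <- i + di; jj <- j + dj
    if (ii < 1 || ii > nr || jj < 1 || jj > nc) next
    if (grid[ii, jj] == cls && patchIds[ii, jj] != patch) return(FALSE)
  }
  TRUE
}

#' Simulate a categorical raster with known patch layout
#'
#' Places patches by seeded region growing. Patches of the same class are
#' kept non-adjacent (8-neighborhood buffer), so the realized per-class
#' patch count reported in the layout is exact ground truth for the
#' labeling and metrics stages. `aggregation` in [0, 1] steers growth
#' compactness: 1 always extends the patch at the frontier cell touching
#' the most patch cells (compact, high AI), 0 picks frontier cells
#' uniformly (ragged growth).
#'
#' @param nRows,nCols grid dimensions.
#' @param classPatches list of specs, each a list/vector with `class`,
#'   `nPatches`, `meanPatchCells`, and optional `aggregation` (default
#'   0.8). Patch sizes are drawn as 1 + Poisson(meanPatchCells - 1).
#' @param cellSize cell edge length in meters.
#' @param seed RNG seed; the whole layout is reproducible under it.
#' @param maxTries placement attempts per patch before giving up.
#' @return list with `raster` (a [CategoricalRaster-class]) and `layout`
#'   (data.frame class, patch, cells actually realized).
#' @examples
#' sim <- simulateRaster(20, 20,
#'   list(list(class = 1, nPatches = 3, meanPatchCells = 6)), seed = 7)
#' sim$layout
#' @export
simulateRaster <- function(nRows, nCols, classPatches, cellSize = 1,
                           seed = 1, maxTries = 200) {
  if (nRows < 1 || nCols < 1) stop("raster dimensions must be >= 1")
  set.seed(seed)
  grid <- matrix(0L, nRows, nCols)
  patchIds <- matrix(0L, nRows, nCols)
  layout <- list()
  nextId <- 0L
  for (spec in classPatches) {
    spec <- as.list(spec)
    cls <- as.integer(spec$class)
    if (cls <= 0) stop("patch classes must be positive (0 is background)")
    agg <- if (is.null(spec$aggregation)) 0.8 else spec$aggregation
    sizes <- 1L + stats::rpois(spec$nPatches, max(0, spec$meanPatchCells - 1))
    if (sum(sizes) > nRows * nCols)
      stop("requested patch cells exceed the grid size")
    for (p in seq_len(spec$nPatches)) {
      nextId <- nextId + 1L
      placed <- FALSE
      for (try in seq_len(maxTries)) {
        free <- which(grid == 0L)
        if (!length(free)) break
        cell <- free[sample.int(length(free), 1L)]
        i <- (cell - 1L) %% nRows + 1L
        j <- (cell - 1L) %/% nRows + 1L
        if (!.validCell(i, j, grid, patchIds, cls, nextId)) next
        placed <- TRUE
        grid[i, j] <- cls
        patchIds[i, j] <- nextId
        cells <- matrix(c(i, j), 1)
        while (nrow(cells) < sizes[p]) {
          # frontier: valid free cells 4-adjacent to the patch
          front <- unique(do.call(rbind, lapply(seq_len(nrow(cells)),
            function(k) {
              i0 <- cells[k, 1]; j0 <- cells[k, 2]
              rbind(c(i0 - 1, j0), c(i0 + 1, j0), c(i0, j0 - 1),
                    c(i0, j0 + 1))
            })))
          keep <- front[, 1] >= 1 & front[, 1] <= nRows &
                  front[, 2] >= 1 & front[, 2] <= nCols
          front <- front[keep, , drop = FALSE]
          keep <- vapply(seq_len(nrow(front)), function(k)
            .validCell(front[k, 1], front[k, 2], grid, patchIds, cls,
                       nextId), logical(1))
          front <- front[keep, , drop = FALSE]
          if (!nrow(front)) break  # boxed in: accept the realized size
          if (stats::runif(1) < agg) {
            nb <- vapply(seq_len(nrow(front)), function(k) {
              sum(abs(cells[, 1] - front[k, 1]) +
                  abs(cells[, 2] - front[k, 2]) == 1)
            }, numeric(1))
            pick <- which(nb == max(nb))
            pick <- pick[sample.int(length(pick), 1L)]
          } else pick <- sample.int(nrow(front), 1L)
          i1 <- front[pick, 1]; j1 <- front[pick, 2]
          grid[i1, j1] <- cls
          patchIds[i1, j1] <- nextId
          cells <- rbind(cells, c(i1, j1))
        }
        layout[[nextId]] <- data.frame(class = cls, patch = nextId,
                                       cells = nrow(cells))
        break
      }
      if (!placed)
        stop("could not place patch ", p, " of class ", cls, " after ",
             maxTries, " tries: same-class separation constraint ",
             "leaves no admissible seed cell")
    }
  }
  list(raster = categoricalRaster(grid, cellSize = cellSize),
       layout = do.call(rbind, layout))
}
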