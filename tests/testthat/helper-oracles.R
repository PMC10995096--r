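# Independent brute-force oracles, deliberately written in a different
# style from the package implementations (cell-by-cell loops, queue-based
# flood fill, finite differences).

# flood-fill labeling: returns a list of integer vectors, each the
# (column-major) cell indices of one patch of `classLabel`
floodFillOracle <- function(grid, classLabel, connectivity = 8) {
  nr <- nrow(grid); nc <- ncol(grid)
  seen <- matrix(FALSE, nr, nc)
  offs <- if (connectivity == 8)
    list(c(-1, -1), c(-1, 0), c(-1, 1), c(0, -1), c(0, 1), c(1, -1),
         c(1, 0), c(1, 1))
  else list(c(-1, 0), c(1, 0), c(0, -1), c(0, 1))
  patches <- list()
  for (j in seq_len(nc)) for (i in seq_len(nr)) {
    if (is.na(grid[i, j]) || grid[i, j] != classLabel || seen[i, j]) next
    queue <- list(c(i, j))
    seen[i, j] <- TRUE
    cells <- integer(0)
    while (length(queue)) {
      cur <- queue[[1]]; queue <- queue[-1]
      cells <- c(cells, (cur[2] - 1) * nr + cur[1])
      for (d in offs) {
        ii <- cur[1] + d[1]; jj <- cur[2] + d[2]
        if (ii < 1 || ii > nr || jj < 1 || jj > nc) next
        if (!seen[ii, jj] && !is.na(grid[ii, jj]) &&
            grid[ii, jj] == classLabel) {
          seen[ii, jj] <- TRUE
          queue <- c(queue, list(c(ii, jj)))
        }
      }
    }
    patches <- c(patches, list(sort(cells)))
  }
  patches
}

# all six class metrics by direct enumeration of cells, edges and
# adjacencies
metricsOracle <- function(grid, classLabel, cellSize = 1,
                          connectivity = 8, nodata = -1L) {
  nr <- nrow(grid); nc <- ncol(grid)
  patches <- floodFillOracle(grid, classLabel, connectivity)
  np <- length(patches)
  landCells <- 0L
  for (j in seq_len(nc)) for (i in seq_len(nr))
    if (!is.na(grid[i, j]) && grid[i, j] != nodata)
      landCells <- landCells + 1L
  landKm2 <- landCells * cellSize^2 / 1e6
  if (np == 0)
    return(list(np = 0L, pd = 0, area_mn = NA_real_, lpi = NA_real_,
                lsi = NA_real_, ai = NA_real_))
  sizes <- vapply(patches, length, integer(1))
  A <- sum(sizes)
  g <- 0L; edge <- 0L
  for (j in seq_len(nc)) for (i in seq_len(nr)) {
    if (is.na(grid[i, j]) || grid[i, j] != classLabel) next
    for (d in list(c(-1, 0), c(1, 0), c(0, -1), c(0, 1))) {
      ii <- i + d[1]; jj <- j + d[2]
      like <- ii >= 1 && ii <= nr && jj >= 1 && jj <= nc &&
        !is.na(grid[ii, jj]) && grid[ii, jj] == classLabel
      if (!like) edge <- edge + 1L         # boundary or unlike neighbor
      else if (d[1] > 0 || d[2] > 0) g <- g + 1L  # count each pair once
    }
  }
  n <- floor(sqrt(A)); m <- A - n^2
  gmax <- if (m == 0) 2 * n * (n - 1)
          else if (m <= n) 2 * n * (n - 1) + 2 * m - 1
          else 2 * n * (n - 1) + 2 * m - 2
  list(np = np, pd = np / landKm2,
       area_mn = mean(sizes) * cellSize^2 / 1e4,
       lpi = 100 * max(sizes) / landCells,
       lsi = 0.25 * edge / sqrt(A),
       ai = if (gmax > 0) 100 * g / gmax else NA_real_)
}

expect_metrics_equal <- function(got, want, tol = 1e-10) {
  for (f in c("np", "pd", "area_mn", "lpi", "lsi", "ai")) {
    if (is.na(want[[f]])) expect_true(is.na(got[[f]]))
    else expect_equal(got[[f]], want[[f]], tolerance = tol)
  }
}

# straight-line re-implementation of the forward pass
forwardOracle <- function(net, x, outputActivation = "sigmoid") {
  X <- rbind(x)
  out <- matrix(NA_real_, nrow(X), length(net@b2))
  for (s in seq_len(nrow(X))) {
    u <- numeric(length(net@b1))
    for (h in seq_along(u)) {
      a <- net@b1[h]
      for (i in seq_len(ncol(X))) a <- a + net@v1[h, i] * X[s, i]
      u[h] <- 1 / (1 + exp(-a))
    }
    for (o in seq_along(net@b2)) {
      z <- net@b2[o]
      for (h in seq_along(u)) z <- z + net@w2[o, h] * u[h]
      out[s, o] <- if (outputActivation == "linear") z else 1 / (1 + exp(-z))
    }
  }
  out
}

# central finite-difference gradient of bpError over the flat gene vector
fdGradient <- function(net, x, y, outputActivation = "sigmoid",
                       eps = 1e-6) {
  genes <- encodeParams(net)
  ni <- ncol(net@v1); nh <- nrow(net@v1); no <- nrow(net@w2)
  vapply(seq_along(genes), function(k) {
    gp <- genes; gp[k] <- gp[k] + eps
    gm <- genes; gm[k] <- gm[k] - eps
    (bpError(decodeParams(gp, ni, nh, no), x, y, outputActivation) -
     bpError(decodeParams(gm, ni, nh, no), x, y, outputActivation)) /
      (2 * eps)
  }, numeric(1))
}

randomRaster <- function(nr, nc, nClasses = 2, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  categoricalRaster(matrix(sample.int(nClasses + 1L, nr * nc,
                                      replace = TRUE) - 1L, nr, nc))
}
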