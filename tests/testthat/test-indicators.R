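test_that("AHP recovers weights from consistent comparison matrices", {
  # indifference: equal weights, perfectly consistent
  res <- ahpWeights(matrix(1, 4, 4))
  expect_equal(res$weights, rep(0.25, 4))
  expect_equal(res$consistencyRatio, 0, tolerance = 1e-12)

  # matrix built from known weights is consistent and returns them
  w <- c(0.5, 0.3, 0.2)
  P <- outer(w, w, "/")
  res <- ahpWeights(P)
  expect_equal(res$weights, w, tolerance = 1e-12)
  expect_equal(res$lambdaMax, 3, tolerance = 1e-12)
  expect_true(res$consistent)
})

test_that("AHP agrees with a power-iteration oracle", {
  P <- matrix(c(1, 2, 4, 1/2, 1, 2, 1/4, 1/2, 1), 3, 3, byrow = TRUE)
  res <- ahpWeights(P)
  # oracle: plain power iteration for the principal eigenpair
  v <- rep(1, 3)
  for (i in 1:200) v <- as.numeric(P %*% v) / sqrt(sum((P %*% v)^2))
  lam <- as.numeric(t(v) %*% P %*% v / sum(v^2))
  expect_equal(res$weights, v / sum(v), tolerance = 1e-10)
  expect_equal(res$lambdaMax, lam, tolerance = 1e-10)
})

test_that("AHP validates its input", {
  bad <- matrix(c(1, 2, 3, 1, 1, 2, 1, 1, 1), 3, 3)
  expect_error(ahpWeights(bad), "reciprocal")
  expect_error(ahpWeights(matrix(1, 1, 1)), "order")
  expect_error(ahpWeights(matrix(c(1, -2, -1/2, 1), 2, 2)), "positive")
})

test_that("min-max normalization honors polarity and flags constants", {
  x <- cbind(a = c(2, 4, 6), b = c(2, 4, 6), c = c(5, 5, 5))
  norm <- normalizeIndicators(x, polarity = c("benefit", "cost", "benefit"))
  expect_equal(unname(norm[, "a"]), c(0, 0.5, 1))
  expect_equal(unname(norm[, "b"]), c(1, 0.5, 0))
  expect_equal(unname(norm[, "c"]), c(0.5, 0.5, 0.5))
  expect_equal(attr(norm, "constant"), c(FALSE, FALSE, TRUE))
})

test_that("the printed urbanization column normalizes to hand values", {
  u <- loadFixture("table3")$U
  norm <- normalizeIndicators(cbind(u))
  expect_equal(unname(norm[, 1]), (u - 74.30) / 7.70, tolerance = 1e-12)
})

test_that("normalization round-trips through its inverse", {
  set.seed(5)
  x <- matrix(rnorm(40, 50, 9), 10, 4)
  stats <- minMaxFit(x)
  norm <- minMaxApply(stats, x)
  denorm <- sweep(sweep(norm, 2, stats$hi - stats$lo, "*"), 2,
                  stats$lo, "+")
  expect_equal(denorm, x, tolerance = 1e-12)
})

test_that("the composite index is the percent-weighted indicator sum", {
  expect_equal(computeLQCI(rep(0, 29), rep(2, 29)), 0)
  w <- unname(indicatorWeights(loadFixture("table2")))
  expect_equal(computeLQCI(rep(1, 29), w), 55.923)
  expect_equal(computeLQCI(c(0.5, 0.5, 1), c(10, 20, 30)), 45)
  expect_error(computeLQCI(c(0.5, 0.5), c(10, 20, 30)), "length")
  expect_error(computeLQCI(c(1.5, 0, 0), c(1, 1, 1)), "0, 1")
})

test_that("the composite index is monotone in indicator polarity", {
  set.seed(8)
  w <- runif(5, 0.5, 5)
  v <- runif(5)
  base <- computeLQCI(v, w)
  for (j in 1:5) {
    up <- v
    up[j] <- min(1, v[j] + 0.1)
    expect_gte(computeLQCI(up, w), base)  # benefit direction
  }
})

test_that("the experiment container carries the whole indicator pathway", {
  sim <- simulateIndicatorSeries(nYears = 5, nIndicators = 3,
                                 trueWeights = c(10, 20, 30), noiseSd = 0.5,
                                 seed = 2)
  se <- sim$experiment
  expect_s4_class(se, "SummarizedExperiment")
  expect_equal(dim(se), c(3L, 5L))
  expect_equal(unname(computeLQCI(se)), unname(sim$truth),
               tolerance = 1e-12)
})

test_that("level assignment reproduces the printed boundaries", {
  sc <- levelScale(28.77, 43.72)
  expect_equal(assignLevel(28.77, sc), "IV")   # lowest score, clamped
  expect_equal(assignLevel(40.27, sc), "I")    # ceil(3.077) = 4
  expect_equal(assignLevel(43.72, sc), "I")    # highest score
  expect_error(assignLevel(NA_real_, sc), "finite")
})

test_that("level assignment is monotone and total on the scale", {
  sc <- levelScale(0, 10, nLevels = 4)
  xs <- seq(0, 10, by = 0.05)
  lev <- assignLevel(xs, sc)
  ord <- match(lev, c("IV", "III", "II", "I"))  # worst..best as 1..4
  expect_true(all(diff(ord) >= 0))
  expect_setequal(unique(lev), c("I", "II", "III", "IV"))
  # scores beyond the scale clamp to the extreme levels
  expect_equal(assignLevel(-3, sc), "IV")
  expect_equal(assignLevel(12, sc), "I")
})
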