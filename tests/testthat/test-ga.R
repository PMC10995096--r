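# small shared problem: 3 samples from an exactly representable 1-1-1 net
toyProblem <- function() {
  target <- decodeParams(c(0.8, -0.2, 0.6, 0.1), 1, 1, 1)
  x <- cbind(c(0, 0.5, 1))
  list(x = x, y = as.numeric(bpForward(target, x)), genes = c(0.8, -0.2,
                                                              0.6, 0.1))
}

test_that("chromosome encoding round-trips and counts genes correctly", {
  set.seed(21)
  net <- bpInit(4, 3, 2)
  expect_equal(decodeParams(encodeParams(net), 4, 3, 2), net)
  # 2-2-1 topology: 2*2 + 2 + 2*1 + 1 = 9 genes
  expect_length(encodeParams(bpInit(2, 2, 1)), 9)
  expect_error(decodeParams(rep(0, 8), 2, 2, 1), "genes")
  # zero chromosome decodes to all-zero parameters
  zero <- decodeParams(rep(0, 9), 2, 2, 1)
  expect_true(all(zero@v1 == 0) && all(zero@b1 == 0) &&
              all(zero@w2 == 0) && all(zero@b2 == 0))
})

test_that("fitness is 1/(1 + E) of the decoded network", {
  toy <- toyProblem()
  # exact solution: E = 0, fitness 1
  expect_equal(gaFitness(toy$genes, toy$x, toy$y, 1, 1, 1), 1)
  # engineered unit error: linear output, constant prediction 0.5,
  # single target offset by sqrt(2) gives E = 1, fitness 0.5
  genes <- c(0, 0, 1, 0)
  y1 <- 0.5 + sqrt(2)
  expect_equal(gaFitness(genes, cbind(0.3), y1, 1, 1, 1, "linear"), 0.5)
  # cross-check against the error function on random chromosomes
  set.seed(3)
  for (i in 1:5) {
    g <- runif(9, -1, 1)
    X <- matrix(runif(6), 3); y <- runif(3)
    expect_equal(gaFitness(g, X, y, 2, 2, 1),
                 1 / (1 + bpError(decodeParams(g, 2, 2, 1), X, y)))
  }
})

test_that("roulette selection draws proportionally to fitness", {
  set.seed(12)
  # fitnesses 3:1 -> P(first) = 0.75; 3-sigma binomial band on 1e5 draws
  draws <- replicate(1e5, rouletteSelect(c(3, 1)))
  phat <- mean(draws == 1)
  expect_lt(abs(phat - 0.75), 3 * sqrt(0.75 * 0.25 / 1e5))
  # uniform fitness -> uniform selection
  draws <- replicate(1e5, rouletteSelect(rep(2, 4)))
  for (k in 1:4)
    expect_lt(abs(mean(draws == k) - 0.25), 3 * sqrt(0.25 * 0.75 / 1e5))
  # degenerate cases
  expect_equal(rouletteSelect(5), 1L)
  expect_error(rouletteSelect(c(0, 0)), "positive")
})

test_that("arithmetic crossover mixes convexly and respects Pe", {
  pa <- c(0.5, -0.5, 0.9); pb <- c(-0.1, 0.3, -0.7)
  set.seed(2)
  expect_identical(arithCrossover(pa, pb, Pe = 0), list(pa, pb))
  ch <- arithCrossover(pa, pa, Pe = 1)
  expect_equal(ch[[1]], pa)
  expect_equal(ch[[2]], pa)
  ch <- arithCrossover(pa, pb, Pe = 1, alpha = 0.5)
  expect_equal(ch[[1]], (pa + pb) / 2)
  expect_equal(ch[[2]], (pa + pb) / 2)
  # convexity keeps children inside the gene bounds
  for (i in 1:20) {
    ch <- arithCrossover(pa, pb, Pe = 1)
    expect_true(all(abs(unlist(ch)) < 1))
  }
  expect_error(arithCrossover(pa, pb[1:2]), "equal length")
})

test_that("mutation resamples uniformly within bounds", {
  g <- seq(-0.9, 0.9, length.out = 50)
  set.seed(9)
  expect_identical(uniformMutate(g, Pm = 0), g)
  m <- uniformMutate(g, Pm = 1)
  expect_true(all(m > -1 & m < 1))
  # full mutation is a fresh uniform draw
  big <- replicate(200, uniformMutate(numeric(50), Pm = 1))
  ks <- suppressWarnings(ks.test(as.vector(big), "punif", -1, 1))
  expect_gt(ks$p.value, 0.001)
  # reproducible under seed
  set.seed(77); a <- uniformMutate(g, 0.5)
  set.seed(77); b <- uniformMutate(g, 0.5)
  expect_identical(a, b)
})

test_that("evolution keeps bounds and elitist fitness is monotone", {
  toy <- toyProblem()
  res <- gaEvolve(toy$x, toy$y, 1, 1, 1,
                  config = gaConfig(populationSize = 10, generations = 30),
                  seed = 5)
  expect_true(all(res$genes > -1 & res$genes < 1))
  expect_true(all(diff(res$history$bestFitness) >= 0))
  expect_equal(res$fitness, max(res$history$bestFitness))
  # gen = 0 reports the best of the random initial population
  res0 <- gaEvolve(toy$x, toy$y, 1, 1, 1,
                   config = gaConfig(populationSize = 10, generations = 0),
                   seed = 5)
  expect_equal(nrow(res0$history), 1)
})

test_that("the GA approaches the backpropagation optimum on a toy net", {
  toy <- toyProblem()
  bpCfg <- bpTrainConfig(learningRate = 0.5, targetError = 1e-3,
                         maxEpochs = 20000, outputActivation = "sigmoid")
  bpFit <- bpTrain(bpInit(1, 1, 1, seed = 1), toy$x, toy$y, bpCfg)
  gaE <- vapply(1:10, function(s) {
    res <- gaEvolve(toy$x, toy$y, 1, 1, 1,
                    config = gaConfig(generations = 200), seed = s)
    1 / res$fitness - 1
  }, numeric(1))
  expect_lte(median(gaE), 10 * bpFit$finalError)
})

test_that("GA-BP refinement never worsens the GA-best error", {
  toy <- toyProblem()
  cfg <- bpTrainConfig(learningRate = 0.1, targetError = 1e-8,
                       maxEpochs = 2000)
  fit <- gaBpTrain(toy$x, toy$y, 1, 1, 1,
                   gaCfg = gaConfig(populationSize = 10, generations = 20),
                   trainCfg = cfg, seed = 3)
  gaBestE <- 1 / fit$gaFitness - 1
  expect_lte(fit$finalError, gaBestE + 1e-12)
  # gen = 0 degenerates to plain BP from the best random chromosome
  fit0 <- gaBpTrain(toy$x, toy$y, 1, 1, 1,
                    gaCfg = gaConfig(populationSize = 5, generations = 0),
                    trainCfg = cfg, seed = 3)
  expect_true(is.finite(fit0$finalError))
})

test_that("the hybrid pipeline is reproducible under one master seed", {
  toy <- toyProblem()
  cfg <- bpTrainConfig(maxEpochs = 500)
  a <- gaBpTrain(toy$x, toy$y, 1, 1, 1,
                 gaCfg = gaConfig(generations = 10), trainCfg = cfg,
                 seed = 31)
  b <- gaBpTrain(toy$x, toy$y, 1, 1, 1,
                 gaCfg = gaConfig(generations = 10), trainCfg = cfg,
                 seed = 31)
  expect_identical(a$net@v1, b$net@v1)
  expect_identical(a$gaHistory, b$gaHistory)
  expect_identical(a$errors, b$errors)
})
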