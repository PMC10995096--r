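test_that("sigmoid has the logistic shape and value", {
  expect_equal(sigmoid(0), 0.5)
  x <- seq(-8, 8, by = 0.37)
  expect_equal(sigmoid(x) + sigmoid(-x), rep(1, length(x)),
               tolerance = 1e-14)
  expect_true(all(diff(sigmoid(x)) > 0))
  # 30-digit arbitrary-precision reference value
  expect_equal(sigmoid(1), 0.731058578630004879251159241822,
               tolerance = 1e-12)
})

test_that("the forward pass matches hand values and a line-by-line oracle", {
  zero <- decodeParams(rep(0, 9), 2, 2, 1)
  expect_equal(as.numeric(bpForward(zero, c(0.3, 0.8))), 0.5)

  # 1-1-1 identity-ish net: x = 0 -> hidden 0.5 -> linear output 0.5
  net <- decodeParams(c(1, 0, 1, 0), 1, 1, 1)
  expect_equal(as.numeric(bpForward(net, 0, "linear")), 0.5)

  set.seed(14)
  for (topo in list(c(3, 4, 1), c(5, 2, 3))) {
    n <- topo[1] * topo[2] + topo[2] + topo[2] * topo[3] + topo[3]
    net <- decodeParams(runif(n, -1, 1), topo[1], topo[2], topo[3])
    X <- matrix(runif(4 * topo[1]), 4)
    for (act in c("sigmoid", "linear"))
      expect_equal(bpForward(net, X, act), forwardOracle(net, X, act),
                   tolerance = 1e-12)
  }
  expect_error(bpForward(net, matrix(0, 1, 2)), "expects")
})

test_that("the error function is the half sum of squared residuals", {
  # zero first-layer weights, linear output w2 = 1, b2 = 0: yhat = 0.5
  net <- decodeParams(c(0, 0, 1, 0), 1, 1, 1)
  x <- cbind(c(0.2, 0.9))
  expect_equal(bpError(net, x, c(0.5, 0.5), "linear"), 0)  # perfect
  # residuals 0.5 - 0.3 = 0.2 and 0.5 - 0.9 = -0.4
  expect_equal(bpError(net, x, c(0.3, 0.9), "linear"),
               0.5 * (0.2^2 + 0.4^2))
})

test_that("analytic gradients match central finite differences", {
  set.seed(99)
  for (topo in list(c(2, 3, 1), c(5, 8, 2), c(1, 1, 1))) {
    n <- topo[1] * topo[2] + topo[2] + topo[2] * topo[3] + topo[3]
    net <- decodeParams(runif(n, -1, 1), topo[1], topo[2], topo[3])
    X <- matrix(runif(6 * topo[1]), 6)
    Y <- matrix(runif(6 * topo[3], 0.2, 0.8), 6)
    for (act in c("sigmoid", "linear")) {
      g <- bpGradient(net, X, Y, act)
      flat <- c(as.vector(t(g$v1)), g$b1, as.vector(t(g$w2)), g$b2)
      fd <- fdGradient(net, X, Y, act)
      expect_equal(flat, fd, tolerance = 1e-6)
    }
  }
})

test_that("one compiled training step equals one R gradient step", {
  set.seed(4)
  net <- bpInit(3, 4, 1)
  X <- matrix(runif(15), 5)
  y <- runif(5, 0.2, 0.8)
  cfg <- bpTrainConfig(learningRate = 0.05, targetError = 1e-12,
                       maxEpochs = 1)
  got <- bpTrain(net, X, y, cfg)$net
  g <- bpGradient(net, X, y, "sigmoid")
  expect_equal(got@v1, net@v1 - 0.05 * g$v1, tolerance = 1e-12)
  expect_equal(got@b1, net@b1 - 0.05 * g$b1, tolerance = 1e-12)
  expect_equal(got@w2, net@w2 - 0.05 * g$w2, tolerance = 1e-12)
  expect_equal(got@b2, net@b2 - 0.05 * g$b2, tolerance = 1e-12)
})

test_that("training stops immediately when already below target", {
  net <- decodeParams(c(0, 0, 1, 0), 1, 1, 1)  # predicts 0.5 exactly
  fit <- bpTrain(net, cbind(c(0, 1)), c(0.5, 0.5),
                 bpTrainConfig(targetError = 0.001,
                               outputActivation = "linear"))
  expect_equal(fit$epochs, 0)
  expect_true(fit$converged)
  expect_equal(fit$finalError, 0)
})

test_that("a tiny linear-output net trains to convergence", {
  fit <- bpTrain(bpInit(1, 1, 1, seed = 2), cbind(c(0, 1)), c(0.3, 0.7),
                 bpTrainConfig(learningRate = 0.5, targetError = 1e-4,
                               maxEpochs = 50000,
                               outputActivation = "linear"))
  expect_true(fit$converged)
  expect_lt(fit$finalError, 1e-4)
})

test_that("training is bit-reproducible and momentum-free descent is monotone", {
  set.seed(7)
  X <- matrix(runif(12), 4)
  y <- runif(4, 0.3, 0.7)
  cfg <- bpTrainConfig(learningRate = 0.2, momentum = 0,
                       targetError = 1e-9, maxEpochs = 300)
  a <- bpTrain(bpInit(3, 3, 1, seed = 11), X, y, cfg)
  b <- bpTrain(bpInit(3, 3, 1, seed = 11), X, y, cfg)
  expect_identical(a$net@v1, b$net@v1)
  expect_identical(a$errors, b$errors)
  expect_true(all(diff(a$errors) <= 1e-12))
})

test_that("divergent training raises an error naming the epoch", {
  expect_error(
    bpTrain(bpInit(1, 1, 1, seed = 1), cbind(c(0, 1)), c(1e6, -1e6),
            bpTrainConfig(learningRate = 1e6, maxEpochs = 5000,
                          outputActivation = "linear")),
    "diverged.*epoch")
})

test_that("target scaling inverts exactly and rejects constants", {
  y <- c(28.77, 35.65, 43.72)
  ts <- targetScale(y)
  expect_equal(range(ts$scale(y)), c(0.1, 0.9))
  expect_equal(ts$invert(ts$scale(y)), y, tolerance = 1e-12)
  expect_error(targetScale(c(2, 2)), "constant")
})
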