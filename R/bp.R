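#' Sigmoid activation
#'
#' f(x) = 1 / (1 + exp(-x)), the logistic function used by all hidden
#' units (and optionally the output unit) of the network. Strictly
#' increasing, with f(-x) = 1 - f(x); saturates to 0/1 for large |x|.
#'
#' @param x numeric.
#' @return Values in (0, 1).
#' @examples
#' sigmoid(0)  # 0.5
#' @export
sigmoid <- function(x) 1 / (1 + exp(-x))

#' Create a network with seeded random parameters
#'
#' Weights and biases are drawn uniformly from (-1, 1) — the same bounds
#' the genetic algorithm searches — so a plain-BP run and a GA-BP run
#' explore the same initial parameter space.
#'
#' @param nIn,nHidden,nOut layer sizes; the study's topology is 17-6-1.
#' @param seed RNG seed; if `NULL` the current RNG state is used.
#' @return A [BPNetwork-class].
#' @examples
#' bpInit(17, 6, 1, seed = 1)
#' @export
bpInit <- function(nIn = 17L, nHidden = 6L, nOut = 1L, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  new("BPNetwork",
      v1 = matrix(runif(nHidden * nIn, -1, 1), nHidden, nIn),
      b1 = runif(nHidden, -1, 1),
      w2 = matrix(runif(nOut * nHidden, -1, 1), nOut, nHidden),
      b2 = runif(nOut, -1, 1))
}

# X as samples x nIn matrix; returns list(u = hidden, yhat = output),
# both samples x units
bpForwardFull <- function(net, X, outputActivation = "sigmoid") {
  X <- rbind(X)  # vector -> 1-row matrix
  if (ncol(X) != ncol(net@v1))
    stop("input has ", ncol(X), " columns but the network expects ",
         ncol(net@v1))
  U <- sigmoid(sweep(X %*% t(net@v1), 2, net@b1, "+"))
  Z <- sweep(U %*% t(net@w2), 2, net@b2, "+")
  list(u = U, yhat = if (outputActivation == "linear") Z else sigmoid(Z))
}

#' Network forward pass
#'
#' Hidden activations are `sigmoid(v1 x + b1)`; the output is
#' `w2 u + b2` passed through the output activation.
#'
#' @param net a [BPNetwork-class].
#' @param x input vector, or a samples-by-inputs matrix.
#' @param outputActivation "sigmoid" or "linear".
#' @return Matrix of outputs, one row per sample.
#' @export
bpForward <- function(net, x, outputActivation = "sigmoid") {
  bpForwardFull(net, x, outputActivation)$yhat
}

#' Training error E
#'
#' The half-sum-of-squares objective E = 1/2 sum ||y - yhat||^2 over all
#' samples; 0 exactly when every prediction is exact.
#'
#' @inheritParams bpForward
#' @param y expected outputs, one row (or element) per sample.
#' @export
bpError <- function(net, x, y, outputActivation = "sigmoid") {
  yhat <- bpForward(net, x, outputActivation)
  0.5 * sum((yhat - as.matrix(y))^2)
}

#' Analytic gradient of E
#'
#' Reference (R-level) backpropagation gradient of [bpError()] with
#' respect to every parameter; the compiled training loop must agree with
#' it, and it must agree with central finite differences.
#'
#' @inheritParams bpError
#' @return list of gradients `v1`, `b1`, `w2`, `b2`.
#' @export
bpGradient <- function(net, x, y, outputActivation = "sigmoid") {
  X <- rbind(x)
  Y <- as.matrix(y)
  fw <- bpForwardFull(net, X, outputActivation)
  resid <- fw$yhat - Y                      # samples x nOut
  dZ <- if (outputActivation == "linear") resid
        else resid * fw$yhat * (1 - fw$yhat)
  dU <- (dZ %*% net@w2) * fw$u * (1 - fw$u) # samples x nHidden
  list(v1 = t(dU) %*% X, b1 = colSums(dU),
       w2 = t(dZ) %*% fw$u, b2 = colSums(dZ))
}

#' Train a network by full-batch backpropagation
#'
#' Full-batch gradient descent with classical momentum on E, stopping as
#' soon as E drops below the target error or the epoch cap is reached.
#' Deterministic given the initial network and configuration (no RNG is
#' consumed). Divergence (non-finite E) raises an error naming the epoch.
#'
#' @param net initial [BPNetwork-class].
#' @param x samples-by-inputs matrix of normalized inputs.
#' @param y expected outputs, one row/element per sample.
#' @param config a [BPTrainConfig-class].
#' @return list with `net` (trained [BPNetwork-class]), `errors` (E per
#'   evaluated epoch), `epochs` (updates performed), `finalError`,
#'   `converged`.
#' @examples
#' xy <- cbind(c(0, 1))
#' fit <- bpTrain(bpInit(1, 1, 1, seed = 1), xy, c(0.3, 0.7),
#'                bpTrainConfig(learningRate = 0.5, maxEpochs = 2000,
#'                              outputActivation = "linear"))
#' fit$finalError
#' @export
bpTrain <- function(net, x, y, config = bpTrainConfig()) {
  stopifnot(is(net, "BPNetwork"), is(config, "BPTrainConfig"))
  validObject(config)
  X <- rbind(x)
  Y <- as.matrix(y)
  if (nrow(Y) != nrow(X)) stop("x and y must have the same number of samples")
  res <- cpp_bp_train(net@v1, net@b1, net@w2, net@b2, X, Y,
                      config@learningRate, config@momentum,
                      config@maxEpochs, config@targetError,
                      config@outputActivation == "linear")
  out <- new("BPNetwork", v1 = res$v1, b1 = res$b1, w2 = res$w2,
             b2 = res$b2)
  list(net = out, errors = res$errors, epochs = res$epochs,
       finalError = res$finalError, converged = res$converged)
}

#' Affine target scaling for sigmoid outputs
#'
#' Maps raw targets min-max linearly onto [lower, upper] (default
#' [0.1, 0.9]) so that a sigmoid output unit can reach them without
#' saturating, and provides the inverse for reporting predictions on the
#' original scale. The statistics are those of the data handed in — fit it
#' on training data only.
#'
#' @param y raw target values.
#' @param lower,upper bounds of the scaled range.
#' @return list with `scale(y)` and `invert(s)` functions plus the stored
#'   `min`/`max`.
#' @export
targetScale <- function(y, lower = 0.1, upper = 0.9) {
  lo <- min(y); hi <- max(y)
  if (hi == lo) stop("targets are constant; scaling is undefined")
  span <- (upper - lower) / (hi - lo)
  list(min = lo, max = hi,
       scale = function(v) lower + (v - lo) * span,
       invert = function(s) lo + (s - lower) / span)
}

#' @export
setMethod("show", "BPNetwork", function(object) {
  cat(sprintf("BPNetwork %d-%d-%d (%d parameters)\n", ncol(object@v1),
              nrow(object@v1), nrow(object@w2),
              length(object@v1) + length(object@b1) + length(object@w2) +
                length(object@b2)))
})
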