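#' Flatten network parameters into a chromosome
#'
#' Gene ordering is fixed and documented: `v1` row-major (hidden unit by
#' hidden unit across all inputs), then `b1`, then `w2` row-major, then
#' `b2`. `decodeParams(encodeParams(net), ...)` is an exact round trip.
#'
#' @param net a [BPNetwork-class].
#' @return Numeric gene vector of length
#'   `nHidden * (nIn + nOut) + nHidden + nOut`.
#' @export
encodeParams <- function(net) {
  stopifnot(is(net, "BPNetwork"))
  c(as.vector(t(net@v1)), net@b1, as.vector(t(net@w2)), net@b2)
}

#' @rdname encodeParams
#' @param genes numeric chromosome.
#' @param nIn,nHidden,nOut the network topology the genes encode.
#' @export
decodeParams <- function(genes, nIn = 17L, nHidden = 6L, nOut = 1L) {
  nGenes <- nHidden * (nIn + nOut) + nHidden + nOut
  if (length(genes) != nGenes)
    stop("chromosome has ", length(genes), " genes; topology ", nIn, "-",
         nHidden, "-", nOut, " needs ", nGenes)
  i <- 0L
  take <- function(n) { out <- genes[(i + 1L):(i + n)]; i <<- i + n; out }
  new("BPNetwork",
      v1 = matrix(take(nHidden * nIn), nHidden, nIn, byrow = TRUE),
      b1 = take(nHidden),
      w2 = matrix(take(nOut * nHidden), nOut, nHidden, byrow = TRUE),
      b2 = take(nOut))
}

#' GA fitness of a chromosome
#'
#' fitness = 1 / (1 + E) with E the network training error of the decoded
#' chromosome on the samples: strictly decreasing in E, in (0, 1], and 1
#' exactly when the decoded network predicts every sample perfectly.
#'
#' @inheritParams decodeParams
#' @param x,y training samples (normalized inputs, scaled targets).
#' @param outputActivation passed to [bpError()].
#' @export
gaFitness <- function(genes, x, y, nIn = 17L, nHidden = 6L, nOut = 1L,
                      outputActivation = "sigmoid") {
  net <- decodeParams(genes, nIn, nHidden, nOut)
  1 / (1 + bpError(net, x, y, outputActivation))
}

#' Roulette-wheel selection
#'
#' Draws one population index with probability proportional to fitness.
#' Consumes the R RNG stream; seed callers with `set.seed()`.
#'
#' @param fitness positive fitness values.
#' @return Selected index.
#' @export
rouletteSelect <- function(fitness) {
  if (any(fitness < 0) || sum(fitness) <= 0)
    stop("fitness values must be non-negative with a positive sum")
  if (length(fitness) == 1L) return(1L)
  sample.int(length(fitness), 1L, prob = fitness)
}

#' Arithmetic crossover of two parents
#'
#' With probability `Pe`, children are the convex combinations
#' `a*pa + (1-a)*pb` and `a*pb + (1-a)*pa` with a single `a ~ U(0, 1)`
#' drawn for the pair; otherwise the parents are copied unchanged.
#' Convexity keeps the children within the (-1, 1) gene bounds.
#'
#' @param pa,pb equal-length parent chromosomes.
#' @param Pe crossover probability.
#' @param alpha optionally force the mixing coefficient (testing hook).
#' @return list of two children.
#' @export
arithCrossover <- function(pa, pb, Pe = 0.3, alpha = NULL) {
  if (length(pa) != length(pb)) stop("parents must have equal length")
  if (runif(1) >= Pe) return(list(pa, pb))
  a <- if (is.null(alpha)) runif(1) else alpha
  list(a * pa + (1 - a) * pb, a * pb + (1 - a) * pa)
}

#' Uniform resampling mutation
#'
#' Each gene is independently, with probability `Pm`, replaced by a fresh
#' draw from U(lower, upper), so the result always respects the gene
#' bounds.
#'
#' @param genes chromosome.
#' @param Pm per-gene mutation probability.
#' @param lower,upper gene bounds.
#' @export
uniformMutate <- function(genes, Pm = 0.1, lower = -1, upper = 1) {
  hit <- runif(length(genes)) < Pm
  if (any(hit)) genes[hit] <- runif(sum(hit), lower, upper)
  genes
}

#' Evolve initial network weights by a real-coded GA
#'
#' Runs `generations` rounds of roulette selection, arithmetic crossover
#' and uniform resampling mutation over a population of flat weight
#' chromosomes bounded in (-1, 1), with the `elitismCount` best carried
#' over unchanged — which makes the best fitness non-decreasing over
#' generations. Returns the best chromosome ever seen.
#'
#' @param x,y training samples (normalized inputs, scaled targets).
#' @param nIn,nHidden,nOut network topology.
#' @param config a [GAConfig-class].
#' @param seed RNG seed; if `NULL` the current RNG state is used.
#' @param outputActivation passed to the fitness evaluation.
#' @return list with `genes` (best chromosome), `fitness`, `net` (decoded
#'   best network), and `history` (data.frame generation, bestFitness,
#'   meanFitness, bestE).
#' @export
gaEvolve <- function(x, y, nIn = 17L, nHidden = 6L, nOut = 1L,
                     config = gaConfig(), seed = NULL,
                     outputActivation = "sigmoid") {
  stopifnot(is(config, "GAConfig"))
  validObject(config)
  if (!is.null(seed)) set.seed(seed)
  N <- config@populationSize
  nGenes <- nHidden * (nIn + nOut) + nHidden + nOut
  pop <- matrix(runif(N * nGenes, -1, 1), N, nGenes)
  evalFit <- function(p) apply(p, 1, gaFitness, x = x, y = y, nIn = nIn,
                               nHidden = nHidden, nOut = nOut,
                               outputActivation = outputActivation)
  fit <- evalFit(pop)
  best <- pop[which.max(fit), ]
  bestFit <- max(fit)
  hist <- data.frame(generation = 0L, bestFitness = bestFit,
                     meanFitness = mean(fit), bestE = 1 / bestFit - 1)
  for (gen in seq_len(config@generations)) {
    newPop <- matrix(NA_real_, N, nGenes)
    nElite <- config@elitismCount
    if (nElite > 0)
      newPop[seq_len(nElite), ] <-
        pop[order(fit, decreasing = TRUE)[seq_len(nElite)], , drop = FALSE]
    i <- nElite + 1L
    while (i <= N) {
      pa <- pop[rouletteSelect(fit), ]
      pb <- pop[rouletteSelect(fit), ]
      ch <- arithCrossover(pa, pb, config@crossoverProb)
      newPop[i, ] <- uniformMutate(ch[[1]], config@mutationProb)
      if (i + 1L <= N)
        newPop[i + 1L, ] <- uniformMutate(ch[[2]], config@mutationProb)
      i <- i + 2L
    }
    pop <- newPop
    fit <- evalFit(pop)
    if (max(fit) > bestFit) {
      bestFit <- max(fit)
      best <- pop[which.max(fit), ]
    }
    hist <- rbind(hist, data.frame(generation = gen, bestFitness = bestFit,
                                   meanFitness = mean(fit),
                                   bestE = 1 / bestFit - 1))
  }
  list(genes = best, fitness = bestFit,
       net = decodeParams(best, nIn, nHidden, nOut), history = hist)
}

#' GA-BP hybrid training
#'
#' The genetic algorithm searches the network's initial weights and
#' thresholds globally; the best chromosome is decoded and handed to
#' backpropagation for local refinement. The final training error is never
#' above the GA-best error because BP only descends from it.
#'
#' @inheritParams gaEvolve
#' @param gaCfg a [GAConfig-class]; `generations = 0` degenerates to plain
#'   BP from the best of a random population.
#' @param trainCfg a [BPTrainConfig-class].
#' @return As [bpTrain()], plus `gaHistory` and `gaFitness`.
#' @export
gaBpTrain <- function(x, y, nIn = 17L, nHidden = 6L, nOut = 1L,
                      gaCfg = gaConfig(), trainCfg = bpTrainConfig(),
                      seed = NULL) {
  ga <- gaEvolve(x, y, nIn, nHidden, nOut, config = gaCfg, seed = seed,
                 outputActivation = trainCfg@outputActivation)
  fit <- bpTrain(ga$net, x, y, trainCfg)
  fit$gaHistory <- ga$history
  fit$gaFitness <- ga$fitness
  fit
}
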