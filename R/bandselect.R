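#' @include AllClasses.R
NULL

## Wrapper band selection. Candidate subsets are binary masks over the
## grid; fitness is the penalized error of the SVM trained on the masked
## bands (lower is better). Exact fitness ties are broken toward the
## smaller subset, which is the penalty's intent carried into comparisons.

.maskKey <- function(mask) paste0(as.integer(mask), collapse = "")

.repairMask <- function(mask) {
  if (!any(mask)) mask[sample(length(mask), 1L)] <- TRUE
  mask
}

## TRUE when (f1, size1) is strictly better than (f2, size2)
.betterThan <- function(f1, s1, f2, s2) {
  f1 < f2 || (f1 == f2 && s1 < s2)
}

.makeEvaluator <- function(fitnessFn, cache = TRUE) {
  env <- new.env(parent = emptyenv())
  function(mask) {
    if (!cache) {
      v <- fitnessFn(mask)
    } else {
      key <- .maskKey(mask)
      v <- env[[key]]
      if (is.null(v)) {
        v <- fitnessFn(mask)
        env[[key]] <- v
      }
    }
    if (is(v, "FitnessValue")) v <- v@value
    v
  }
}

#' Stagnation stopping rule
#'
#' TRUE when the best fitness improved by strictly less than \code{epsilon}
#' over the last \code{patience} iterations of a (non-increasing) trace.
#'
#' @param trace Numeric vector of best-so-far fitness per iteration.
#' @param patience Number of iterations without meaningful improvement.
#' @param epsilon Minimum improvement counted as progress.
#' @return Logical.
#' @export
stoppingRule <- function(trace, patience = 20L, epsilon = 1e-6) {
  n <- length(trace)
  if (n <= patience) return(FALSE)
  (trace[n - patience] - trace[n]) < epsilon
}

#' Genetic-algorithm configuration
#'
#' The optimizer's own parameters; none are dictated by the method itself,
#' so all are exposed. Initialization draws each band with probability
#' \code{initProb}; a sparse-biased default (0.3) reflects the goal of the
#' search, which is small band subsets.
#'
#' @param populationSize Chromosomes per generation (>= 2).
#' @param generations Maximum generations.
#' @param crossoverRate Probability a parent pair recombines.
#' @param mutationRate Probability a child has one random bit flipped.
#' @param elitismCount Best chromosomes copied unchanged each generation.
#' @param crossoverPoints Number of crossover cut points (k-point).
#' @param initProb Per-band inclusion probability at initialization.
#' @param patience,epsilon Stagnation stopping rule parameters.
#' @param seed Integer seed.
#' @return A classed settings list.
#' @export
gaConfig <- function(populationSize = 50L, generations = 100L,
                     crossoverRate = 0.9, mutationRate = 0.2,
                     elitismCount = 2L, crossoverPoints = 1L,
                     initProb = 0.3, patience = 20L, epsilon = 1e-6,
                     seed = 1L) {
  stopifnot(populationSize >= 2L, generations >= 1L,
            crossoverRate >= 0, crossoverRate <= 1,
            mutationRate >= 0, mutationRate <= 1,
            elitismCount >= 0L, elitismCount <= populationSize,
            initProb > 0, initProb <= 1)
  structure(list(populationSize = as.integer(populationSize),
                 generations = as.integer(generations),
                 crossoverRate = crossoverRate, mutationRate = mutationRate,
                 elitismCount = as.integer(elitismCount),
                 crossoverPoints = as.integer(crossoverPoints),
                 initProb = initProb, patience = as.integer(patience),
                 epsilon = epsilon, seed = as.integer(seed)),
            class = "gaConfig")
}

.crossover <- function(a, b, k) {
  n <- length(a)
  if (n < 2L) return(list(a, b))
  cuts <- sort(sample(n - 1L, min(k, n - 1L)))
  seg <- cumsum(seq_len(n) %in% (cuts + 1L)) %% 2L == 1L
  c1 <- a; c1[seg] <- b[seg]
  c2 <- b; c2[seg] <- a[seg]
  list(c1, c2)
}

#' Genetic-algorithm band selection
#'
#' Binary-chromosome GA minimizing a penalized wrapper fitness: seeded
#' random initialization, size-2 tournament selection, k-point crossover
#' exchanging chromosome segments, single-bit mutation, and generational
#' replacement with elitism. All-zero chromosomes are repaired by
#' activating one random band. Returns the best-ever subset and the
#' per-generation best-fitness trace (non-increasing).
#'
#' @param fitnessFn Function taking a logical band mask and returning a
#'   numeric fitness or \linkS4class{FitnessValue} (lower is better).
#' @param nBandsTotal Number of bands in the grid.
#' @param cfg A \code{\link{gaConfig}}.
#' @param grid Optional \linkS4class{SpectralGrid} to attach wavelengths to
#'   the returned subset.
#' @return List: \code{subset} (\linkS4class{BandSubset}), \code{fitness}
#'   (best value), \code{trace} (best-so-far per generation).
#' @export
gaSelect <- function(fitnessFn, nBandsTotal, cfg = gaConfig(), grid = NULL) {
  evalFit <- .makeEvaluator(fitnessFn)
  n <- as.integer(nBandsTotal)
  withr::with_seed(cfg$seed, {
    pop <- lapply(seq_len(cfg$populationSize), function(i)
      .repairMask(runif(n) < cfg$initProb))
    fit <- vapply(pop, evalFit, numeric(1))
    sz <- vapply(pop, sum, numeric(1))
    bi <- order(fit, sz)[1L]
    best <- list(mask = pop[[bi]], fitness = fit[bi])
    trace <- best$fitness
    for (gen in seq_len(cfg$generations)) {
      ord <- order(fit, sz)
      elite <- pop[head(ord, cfg$elitismCount)]
      children <- list()
      while (length(children) < cfg$populationSize - cfg$elitismCount) {
        pick <- function() {
          ij <- sample(cfg$populationSize, 2L)
          if (.betterThan(fit[ij[1]], sz[ij[1]], fit[ij[2]], sz[ij[2]]))
            ij[1] else ij[2]
        }
        p1 <- pop[[pick()]]; p2 <- pop[[pick()]]
        if (runif(1) < cfg$crossoverRate) {
          cs <- .crossover(p1, p2, cfg$crossoverPoints)
        } else cs <- list(p1, p2)
        for (ch in cs) {
          if (runif(1) < cfg$mutationRate) {
            flip <- sample(n, 1L)
            ch[flip] <- !ch[flip]
          }
          children[[length(children) + 1L]] <- .repairMask(ch)
        }
      }
      pop <- c(elite, children[seq_len(cfg$populationSize -
                                         cfg$elitismCount)])
      fit <- vapply(pop, evalFit, numeric(1))
      sz <- vapply(pop, sum, numeric(1))
      bi <- order(fit, sz)[1L]
      if (.betterThan(fit[bi], sz[bi], best$fitness, sum(best$mask)))
        best <- list(mask = pop[[bi]], fitness = fit[bi])
      trace <- c(trace, best$fitness)
      if (stoppingRule(trace, cfg$patience, cfg$epsilon)) break
    }
    list(subset = bandSubset(which(best$mask), nTotal = n, grid = grid),
         fitness = best$fitness, trace = trace)
  })
}

#' Particle-swarm configuration
#'
#' Velocity update \code{v <- alpha*v + c1*rand*(pbest - x) +
#' c2*rand*(gbest - x)} with the conventional acceleration constants
#' \code{c1 = c2 = 2}; \code{alpha} is the inertia weight.
#'
#' @param nParticles Swarm size.
#' @param iterations Maximum iterations.
#' @param alpha Inertia weight.
#' @param c1,c2 Cognitive and social acceleration constants (default 2).
#' @param vMax Velocity clamp (absolute value).
#' @param initProb Per-band inclusion probability at initialization.
#' @param patience,epsilon Stagnation stopping rule parameters.
#' @param seed Integer seed.
#' @return A classed settings list.
#' @export
psoConfig <- function(nParticles = 30L, iterations = 100L, alpha = 0.72,
                      c1 = 2, c2 = 2, vMax = 4, initProb = 0.3,
                      patience = 20L, epsilon = 1e-6, seed = 1L) {
  stopifnot(nParticles >= 2L, iterations >= 1L, vMax > 0,
            initProb > 0, initProb <= 1)
  structure(list(nParticles = as.integer(nParticles),
                 iterations = as.integer(iterations), alpha = alpha,
                 c1 = c1, c2 = c2, vMax = vMax, initProb = initProb,
                 patience = as.integer(patience), epsilon = epsilon,
                 seed = as.integer(seed)),
            class = "psoConfig")
}

#' Binary particle-swarm band selection
#'
#' Positions are binary band masks; velocities are real per band and follow
#' the standard swarm update. Positions are re-binarized each iteration by
#' the sigmoid-threshold rule (bit set when a uniform draw falls below
#' \code{sigmoid(v)}). pbest/gbest fitness is non-increasing by
#' construction; empty masks are repaired as in the GA.
#'
#' @inheritParams gaSelect
#' @param cfg A \code{\link{psoConfig}}.
#' @return List: \code{subset}, \code{fitness}, \code{trace} (gbest per
#'   iteration), \code{velocities} (final velocity matrix).
#' @export
psoSelect <- function(fitnessFn, nBandsTotal, cfg = psoConfig(),
                      grid = NULL) {
  evalFit <- .makeEvaluator(fitnessFn)
  n <- as.integer(nBandsTotal)
  sig <- function(v) 1 / (1 + exp(-v))
  withr::with_seed(cfg$seed, {
    X <- vapply(seq_len(cfg$nParticles), function(i)
      .repairMask(runif(n) < cfg$initProb), logical(n))
    V <- matrix(runif(n * cfg$nParticles, -1, 1), n, cfg$nParticles)
    fit <- apply(X, 2, evalFit)
    pbest <- X; pbestFit <- fit
    gi <- order(fit, colSums(X))[1L]
    gbest <- X[, gi]; gbestFit <- fit[gi]
    trace <- gbestFit
    for (it in seq_len(cfg$iterations)) {
      r1 <- matrix(runif(n * cfg$nParticles), n)
      r2 <- matrix(runif(n * cfg$nParticles), n)
      V <- cfg$alpha * V +
        cfg$c1 * r1 * (pbest - X) +
        cfg$c2 * r2 * (gbest - X)
      V[V > cfg$vMax] <- cfg$vMax
      V[V < -cfg$vMax] <- -cfg$vMax
      X <- matrix(runif(n * cfg$nParticles), n) < sig(V)
      X <- vapply(seq_len(cfg$nParticles),
                  function(i) .repairMask(X[, i]), logical(n))
      fit <- apply(X, 2, evalFit)
      for (i in seq_len(cfg$nParticles)) {
        if (.betterThan(fit[i], sum(X[, i]), pbestFit[i],
                        sum(pbest[, i]))) {
          pbest[, i] <- X[, i]; pbestFit[i] <- fit[i]
        }
        if (.betterThan(fit[i], sum(X[, i]), gbestFit, sum(gbest))) {
          gbest <- X[, i]; gbestFit <- fit[i]
        }
      }
      trace <- c(trace, gbestFit)
      if (stoppingRule(trace, cfg$patience, cfg$epsilon)) break
    }
    list(subset = bandSubset(which(gbest), nTotal = n, grid = grid),
         fitness = gbestFit, trace = trace, velocities = V)
  })
}

#' Ant-colony configuration
#'
#' @param nAnts Ants per iteration.
#' @param iterations Pheromone update iterations.
#' @param evaporationRate Fraction of pheromone lost per iteration, (0, 1).
#' @param pheromoneWeight,heuristicWeight Exponents on pheromone and
#'   heuristic desirability during subset construction.
#' @param subsetSize Bands each ant selects.
#' @param topK Band counts evaluated from the final ranking
#'   (default 20/40/60/80/100).
#' @param seed Integer seed.
#' @return A classed settings list.
#' @export
acoConfig <- function(nAnts = 10L, iterations = 20L, evaporationRate = 0.2,
                      pheromoneWeight = 1, heuristicWeight = 1,
                      subsetSize = 20L, topK = c(20L, 40L, 60L, 80L, 100L),
                      seed = 1L) {
  stopifnot(nAnts >= 1L, iterations >= 1L,
            evaporationRate > 0, evaporationRate < 1, subsetSize >= 1L)
  structure(list(nAnts = as.integer(nAnts),
                 iterations = as.integer(iterations),
                 evaporationRate = evaporationRate,
                 pheromoneWeight = pheromoneWeight,
                 heuristicWeight = heuristicWeight,
                 subsetSize = as.integer(subsetSize),
                 topK = as.integer(topK), seed = as.integer(seed)),
            class = "acoConfig")
}

## Fisher-ratio band separability: between-class over within-class
## variance, normalized to (0, 1].
.fisherScores <- function(M, labs) {
  cls <- sort(unique(labs))
  grand <- rowMeans(M)
  between <- 0; within <- 0
  for (cl in cls) {
    idx <- which(labs == cl)
    mu <- rowMeans(M[, idx, drop = FALSE])
    between <- between + length(idx) * (mu - grand)^2
    within <- within + (length(idx) - 1L) *
      apply(M[, idx, drop = FALSE], 1, var)
  }
  sc <- between / (within + 1e-8)
  sc / max(sc)
}

#' Ant-colony band ranking
#'
#' Ants repeatedly construct band subsets guided by pheromone and a
#' heuristic desirability (per-band Fisher-ratio class separability,
#' discounted during construction by the mean absolute correlation with the
#' bands already chosen). Each subset is scored by a wrapper SVM on a
#' stratified validation split of the training set and deposits pheromone
#' on its bands in proportion to the achieved accuracy; pheromone
#' evaporates each iteration. The final ranking orders all bands by
#' terminal pheromone (ties by heuristic score, then index), most relevant
#' first.
#'
#' @param train A normalized \linkS4class{LabeledDataset} with >= 2 classes.
#' @param cfg An \code{\link{acoConfig}}.
#' @param svmCfg An \code{\link{svmConfig}} for the wrapper scoring.
#' @param qualityFn Optional function(indices) -> quality in [0, 1]
#'   replacing the SVM wrapper (used to study the dynamics in isolation).
#' @return Integer vector: a permutation of all band indices, most
#'   relevant first.
#' @export
acoRank <- function(train, cfg = acoConfig(), svmCfg = svmConfig(),
                    qualityFn = NULL) {
  labs <- pixelLabels(train)
  if (length(unique(labs)) < 2L)
    stop("band ranking needs at least two classes in the training set")
  M <- spectra(train)
  n <- nrow(M)
  s <- min(cfg$subsetSize, n)
  eta <- .fisherScores(M, labs)
  absCor <- abs(suppressWarnings(cor(t(M))))
  absCor[!is.finite(absCor)] <- 0
  withr::with_seed(cfg$seed, {
    if (is.null(qualityFn)) {
      split <- .stratifiedSplit(labs, 0.7)
      tr <- train[, split]
      va <- train[, !split]
      qualityFn <- function(idx) {
        model <- trainSVM(tr, idx, svmCfg)
        pred <- .predictLabels(model, spectra(va))
        overallAccuracy(confusionCounts(pixelLabels(va), pred, 4L))
      }
    }
    tau <- rep(1, n)
    for (it in seq_len(cfg$iterations)) {
      deposits <- rep(0, n)
      for (ant in seq_len(cfg$nAnts)) {
        chosen <- integer(0)
        avail <- rep(TRUE, n)
        for (step in seq_len(s)) {
          red <- if (length(chosen))
            pmax(1 - rowMeans(absCor[, chosen, drop = FALSE]), 0.05)
          else rep(1, n)
          w <- (tau^cfg$pheromoneWeight) *
            ((eta * red)^cfg$heuristicWeight)
          w[!avail] <- 0
          if (all(w == 0)) w[avail] <- 1
          pick <- sample.int(n, 1L, prob = w)
          chosen <- c(chosen, pick)
          avail[pick] <- FALSE
        }
        q <- qualityFn(sort(chosen))
        deposits[chosen] <- deposits[chosen] + q
      }
      tau <- (1 - cfg$evaporationRate) * tau + deposits
    }
    order(-tau, -eta, seq_len(n))
  })
}

.stratifiedSplit <- function(labs, p) {
  sel <- logical(length(labs))
  for (cl in unique(labs)) {
    idx <- which(labs == cl)
    k <- max(1L, round(p * length(idx)))
    sel[sample(idx, k)] <- TRUE
  }
  sel
}

#' Evaluate the top-k bands of a ranking
#'
#' For each requested k, evaluates the first k ranked bands through the
#' supplied harness (typically a leave-one-patient-out evaluation).
#'
#' @param ranking Integer permutation from \code{\link{acoRank}}.
#' @param topK Band counts to evaluate (entries capped at the ranking
#'   length are dropped with a warning).
#' @param evalHarness Function(indices) -> result (e.g. a
#'   \linkS4class{MetricsReport}).
#' @return Named list of harness results, one per k.
#' @export
acoTopkEvaluate <- function(ranking, topK, evalHarness) {
  bad <- topK > length(ranking)
  if (any(bad)) {
    warning("dropping top-k values exceeding the band count")
    topK <- topK[!bad]
  }
  out <- lapply(topK, function(k) evalHarness(sort(ranking[seq_len(k)])))
  names(out) <- paste0("k", topK)
  out
}

#' Build a penalized wrapper fitness function
#'
#' Returns a closure mapping a logical band mask to the penalized fitness
#' \code{(1 - base) * (1 + lambda/lambdaMax)} of an SVM trained on
#' \code{train} restricted to the masked bands and scored on
#' \code{validation}. \code{base} is the overall accuracy ("oa_p") or the
#' figure of merit over per-class accuracies ("fom_p"). The optimizers
#' cache fitness values by band mask, so identical subsets are never
#' retrained within a run.
#'
#' @param train,validation Normalized \linkS4class{LabeledDataset}s.
#' @param baseMetric "fom_p" or "oa_p".
#' @param svmCfg An \code{\link{svmConfig}}.
#' @return Function(logical mask) -> numeric fitness (lower is better).
#' @export
makeWrapperFitness <- function(train, validation,
                               baseMetric = c("fom_p", "oa_p"),
                               svmCfg = svmConfig()) {
  baseMetric <- match.arg(baseMetric)
  nTotal <- nBands(train)
  valLabs <- pixelLabels(validation)
  valM <- spectra(validation)
  function(mask) {
    idx <- which(mask)
    model <- trainSVM(train, idx, svmCfg)
    pred <- .predictLabels(model, valM)
    cc <- confusionCounts(valLabs, pred, 4L)
    base <- if (baseMetric == "oa_p") {
      overallAccuracy(cc)
    } else {
      sens <- vapply(cc@classes, function(c) sensitivity(cc, c),
                     numeric(1))
      fom(sens[!is.na(sens)])
    }
    penalizedFitness(base, length(idx), nTotal, baseMetric)
  }
}
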