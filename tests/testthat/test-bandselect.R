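## Cheap toy fitness: perfect base metric iff band `target` is included,
## with the size penalty making smaller subsets strictly better.
toyFitness <- function(target, n = 12L) {
  function(mask) {
    base <- as.numeric(mask[target])
    (1 - base) * (1 + sum(mask) / n) + 1e-3 * sum(mask) / n
  }
}

test_that("stagnation stopping rule uses strict improvement", {
  expect_false(stoppingRule(seq(1, 0.5, by = -0.01), 10, 1e-6))
  expect_true(stoppingRule(rep(0.4, 30), 10, 1e-6))
  ## improvement exactly epsilon does not stop (dyadic values, exact in
  ## floating point)
  eps <- 2^-20
  tr <- c(rep(0.5, 10), 0.5 - eps)
  expect_false(stoppingRule(tr, 10, eps))
  expect_false(stoppingRule(c(1, 0.9), 10, 1e-6))
})

test_that("GA converges to the single informative band on a toy oracle", {
  for (s in 1:5) {
    g <- gaSelect(toyFitness(7L), 12,
                  gaConfig(populationSize = 20, generations = 50,
                           seed = s))
    expect_true(7L %in% bandIndices(g$subset))
    expect_lte(nBands(g$subset), 3)
    ## reported fitness is the recomputed fitness of the subset
    mask <- seq_len(12) %in% bandIndices(g$subset)
    expect_equal(g$fitness, toyFitness(7L)(mask))
    ## trace is non-increasing
    expect_true(all(diff(g$trace) <= 0))
  }
})

test_that("GA degenerate configurations behave as defined", {
  ## identical population, no mutation, no crossover: flat trace
  fit <- function(mask) 0.5
  g <- gaSelect(fit, 8, gaConfig(populationSize = 6, generations = 10,
                                 crossoverRate = 0, mutationRate = 0,
                                 patience = 100, seed = 2))
  expect_true(all(g$trace == g$trace[1]))
  ## full elitism: population cannot change
  g2 <- gaSelect(toyFitness(3L, 8L), 8,
                 gaConfig(populationSize = 6, generations = 5,
                          elitismCount = 6, patience = 100, seed = 2))
  expect_true(all(diff(g2$trace) == 0))
})

test_that("PSO converges to the single informative band on a toy oracle", {
  for (s in 1:5) {
    p <- psoSelect(toyFitness(7L), 12,
                   psoConfig(nParticles = 15, iterations = 50, seed = s))
    expect_true(7L %in% bandIndices(p$subset))
    mask <- seq_len(12) %in% bandIndices(p$subset)
    expect_equal(p$fitness, toyFitness(7L)(mask))
    expect_true(all(diff(p$trace) <= 0))
  }
})

test_that("PSO velocities collapse when inertia and accelerations are zero", {
  p <- psoSelect(function(mask) 0.5, 10,
                 psoConfig(nParticles = 8, iterations = 5, alpha = 0,
                           c1 = 0, c2 = 0, patience = 100, seed = 3))
  expect_true(all(p$velocities == 0))
  expect_true(all(diff(p$trace) <= 0))
})

test_that("optimizers find the brute-force optimum on 12-band landscapes", {
  ## weighted-coverage base metric; exhaustive search over all 4095 masks
  nOK <- 0
  masks <- as.matrix(expand.grid(rep(list(c(FALSE, TRUE)), 12)))
  masks <- masks[rowSums(masks) > 0, ]
  for (s in 1:10) {
    set.seed(1000 + s)
    w <- runif(12)
    informative <- sample(12, 3)
    fit <- function(mask) {
      base <- sum(w[intersect(which(mask), informative)]) /
        sum(w[informative])
      (1 - base) * (1 + sum(mask) / 12)
    }
    bf <- min(apply(masks, 1, fit))
    g <- gaSelect(fit, 12, gaConfig(populationSize = 30,
                                    generations = 60, seed = s))
    p <- psoSelect(fit, 12, psoConfig(nParticles = 20, iterations = 60,
                                      seed = s))
    nOK <- nOK + (isTRUE(all.equal(g$fitness, bf)) &&
                    isTRUE(all.equal(p$fitness, bf)))
  }
  expect_gte(nOK, 9)
})

test_that("for equal base metric the optimizers prefer fewer bands", {
  ## base metric perfect whenever band 2 is present: the penalty and the
  ## size tie-break must drive the subset down to the single band
  fit <- function(mask) (1 - as.numeric(mask[2])) * (1 + sum(mask) / 10)
  g <- gaSelect(fit, 10, gaConfig(populationSize = 20, generations = 60,
                                  patience = 60, seed = 4))
  expect_equal(bandIndices(g$subset), 2L)
  p <- psoSelect(fit, 10, psoConfig(nParticles = 15, iterations = 60,
                                    patience = 60, seed = 4))
  expect_equal(bandIndices(p$subset), 2L)
})

test_that("ACO ranking is a permutation that surfaces planted bands", {
  ds <- plantedDataset(1)
  rk <- acoRank(ds, acoConfig(nAnts = 8, iterations = 10, subsetSize = 5,
                              seed = 1))
  expect_setequal(rk, 1:20)
  expect_true(all(c(7, 13) %in% rk[1:4]))
  ## deterministic under the seed
  rk2 <- acoRank(ds, acoConfig(nAnts = 8, iterations = 10, subsetSize = 5,
                               seed = 1))
  expect_identical(rk, rk2)
})

test_that("with full evaporation and no deposits the ranking is heuristic order", {
  ds <- plantedDataset(2)
  rk <- acoRank(ds, acoConfig(nAnts = 3, iterations = 3, subsetSize = 5,
                              evaporationRate = 0.999, seed = 1),
                qualityFn = function(idx) 0)
  ## Fisher-ratio heuristic puts the two planted bands first
  expect_setequal(rk[1:2], c(7L, 13L))
})

test_that("ACO refuses a single-class training set", {
  g <- spectralGrid(seq(440, 902, length.out = 10))
  ds <- labeledDataset(matrix(runif(10 * 40), 10), rep(0L, 40),
                       rep(c("A", "B"), 20), grid = g)
  expect_error(acoRank(ds), "two classes")
})

test_that("top-k evaluation runs the harness once per requested k", {
  got <- acoTopkEvaluate(1:20, c(5, 10, 20), function(idx) length(idx))
  expect_equal(got, list(k5 = 5L, k10 = 10L, k20 = 20L))
  ## k values beyond the band count are dropped with a warning
  expect_warning(out <- acoTopkEvaluate(1:20, c(20, 40),
                                        function(idx) length(idx)),
                 "exceeding")
  expect_named(out, "k20")
})

test_that("the wrapper fitness scores subsets by penalized validation error", {
  ds <- smallScene()
  pids <- patientIds(ds)
  red <- reduceTrainingSet(ds[, pids != "P001"],
                           reductionConfig(5, 4, seed = 9))
  val <- ds[, pids == "P001"]
  fn <- makeWrapperFitness(red, val, "oa_p")
  full <- rep(TRUE, nBands(ds))
  fv <- fn(full)
  expect_s4_class(fv, "FitnessValue")
  expect_equal(fv@nSelected, nBands(ds))
  ## penalized value consistent with an independent evaluation
  r <- runFold(red, val, which(full))
  expect_equal(fitnessValue(fv), (1 - r@oa) * 2)
})
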