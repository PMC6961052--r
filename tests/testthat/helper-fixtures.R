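## Shared fixtures, built once per test run and cached.

.fixtures <- new.env(parent = emptyenv())

fixture <- function(name, build) {
  if (is.null(.fixtures[[name]])) .fixtures[[name]] <- build()
  .fixtures[[name]]
}

## Small normalized max-contrast dataset: 3 patients x 120 px/class.
smallScene <- function() fixture("smallScene", function() {
  sp <- syntheticSceneSpec(nPatients = 3, pixelsPerClassPerPatient = 120,
                           seed = 7)
  suppressWarnings(normalizePixels(smoothSpectra(generateDataset(sp), 5)))
})

## Two-class planted-signal dataset: bands 7 and 13 informative out of 20.
plantedDataset <- function(seed, n = 400) {
  set.seed(seed)
  X <- matrix(runif(20 * n), 20, n)
  y <- rep(0:1, each = n / 2)
  X[7, ] <- X[7, ] + 0.8 * y
  X[13, ] <- X[13, ] - 0.8 * y
  labeledDataset(X, as.integer(y), rep(c("A", "B"), n / 2),
                 grid = spectralGrid(seq(440, 902, length.out = 20)))
}

## Brute-force one-vs-rest counting oracle, written independently of the
## package's vectorized path: explicit loops over samples.
oracleCounts <- function(truth, pred, class) {
  TP <- FP <- TN <- FN <- 0L
  for (i in seq_along(truth)) {
    isPos <- truth[i] == class
    saidPos <- pred[i] == class
    if (isPos && saidPos) TP <- TP + 1L
    else if (!isPos && saidPos) FP <- FP + 1L
    else if (isPos && !saidPos) FN <- FN + 1L
    else TN <- TN + 1L
  }
  c(TP = TP, FP = FP, TN = TN, FN = FN)
}

oracleOA <- function(truth, pred) {
  ok <- 0L
  for (i in seq_along(truth)) if (truth[i] == pred[i]) ok <- ok + 1L
  ok / length(truth)
}

oracleMCC <- function(k) {
  den <- prod(c(k["TP"] + k["FP"], k["TP"] + k["FN"],
                k["TN"] + k["FP"], k["TN"] + k["FN"]))
  if (den == 0) return(0)
  unname((as.numeric(k["TP"]) * k["TN"] - as.numeric(k["FP"]) * k["FN"]) /
           sqrt(den))
}

## FoM by direct double loop over class pairs.
oracleFoM <- function(accs) {
  n <- length(accs)
  s <- 0; np <- 0
  for (i in 1:(n - 1)) for (j in (i + 1):n) {
    s <- s + (accs[i] + accs[j]) / (abs(accs[i] - accs[j]) + 1)
    np <- np + 1
  }
  0.5 * s / np
}
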