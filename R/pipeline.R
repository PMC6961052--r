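#' @include AllClasses.R
NULL

.writeJSON <- function(x, outDir, file) {
  if (is.null(outDir)) return(invisible(NULL))
  if (!dir.exists(outDir)) dir.create(outDir, recursive = TRUE)
  jsonlite::write_json(x, file.path(outDir, file), auto_unbox = TRUE,
                       digits = NA, pretty = TRUE)
}

.reportAsList <- function(r) {
  list(oa = r@oa, fom = r@fom, sensitivity = as.list(r@sensitivity),
       specificity = as.list(r@specificity), mccNorm = as.list(r@mccNorm))
}

#' PF1: sampling-interval analysis
#'
#' Sweeps a list of band counts: for each, decimates the dataset to that
#' count and runs the leave-one-patient-out evaluation both on the full
#' training pixels and on the reduced (k-means + spectral angle) training
#' set, recording accuracy and training time. This exposes the
#' accuracy-versus-bands tradeoff that motivates a reduced operating band
#' count.
#'
#' @param data A normalized \linkS4class{LabeledDataset}.
#' @param bandCounts Band counts to evaluate (default 128/64/32/16/8;
#'   entries exceeding the grid are dropped).
#' @param reduceCfg A \code{\link{reductionConfig}} for the reduced rows.
#' @param svmCfg An \code{\link{svmConfig}}.
#' @param withReduction Evaluate the reduced-training variant as well.
#' @param outDir Optional artifact directory (writes pf1.json).
#' @return data.frame: one row per (band count x training variant) with the
#'   sampling interval, mean/sd OA and elapsed seconds.
#' @export
runPF1 <- function(data, bandCounts = c(128L, 64L, 32L, 16L, 8L),
                   reduceCfg = reductionConfig(), svmCfg = svmConfig(),
                   withReduction = TRUE, outDir = NULL) {
  bandCounts <- bandCounts[bandCounts <= nBands(data)]
  if (!length(bandCounts)) stop("no band counts within the grid")
  rows <- list()
  for (nb in bandCounts) {
    ds <- decimateBands(data, nb)
    si <- samplingInterval(lambdaMin(sGrid(data)), lambdaMax(sGrid(data)),
                          nb)
    variants <- if (withReduction) c(FALSE, TRUE) else FALSE
    for (red in variants) {
      tm <- system.time(
        res <- evaluateLOPO(ds, reduceCfg = if (red) reduceCfg else NULL,
                            svmCfg = svmCfg))["elapsed"]
      oa <- res$summary[res$summary$metric == "oa", ]
      rows[[length(rows) + 1L]] <- data.frame(
        n_bands = nb, sampling_interval_nm = si,
        reduced = red, oa_mean = oa$mean, oa_sd = oa$sd,
        elapsed_s = unname(tm))
    }
  }
  out <- do.call(rbind, rows)
  .writeJSON(out, outDir, "pf1.json")
  out
}

## Per-fold wrapper selection shared by PF2. Returns the selection result
## plus the final test report and the full-band reference report.
.pf2Fold <- function(data, fold, method, fitness, optimCfg, reduceCfg,
                     svmCfg, paperLiteral, seed) {
  pids <- patientIds(data)
  trainAll <- data[, pids %in% fold$trainPatients]
  test <- data[, pids == fold$heldOut]
  grid <- sGrid(data)
  n <- nBands(data)

  if (paperLiteral) {
    fitTrain <- suppressWarnings(reduceTrainingSet(
      trainAll, reductionConfig(reduceCfg$kPerClass,
                                reduceCfg$pixelsPerCentroid,
                                deriveSeed(seed, "reduce"))))
    validation <- test
  } else {
    ## inner validation: hold one training patient out of the reduction
    tp <- sort(fold$trainPatients)
    vp <- tp[1L + deriveSeed(seed, fold$heldOut) %% length(tp)]
    inner <- trainAll[, patientIds(trainAll) != vp]
    fitTrain <- suppressWarnings(reduceTrainingSet(
      inner, reductionConfig(reduceCfg$kPerClass,
                             reduceCfg$pixelsPerCentroid,
                             deriveSeed(seed, "reduce"))))
    validation <- trainAll[, patientIds(trainAll) == vp]
  }
  fitnessFn <- makeWrapperFitness(fitTrain, validation, fitness, svmCfg)

  optimCfg$seed <- deriveSeed(seed, paste0(method, fold$heldOut))
  sel <- if (method == "ga") {
    gaSelect(fitnessFn, n, do.call(gaConfig, optimCfg), grid)
  } else {
    psoSelect(fitnessFn, n, do.call(psoConfig, optimCfg), grid)
  }

  finalTrain <- suppressWarnings(reduceTrainingSet(
    trainAll, reductionConfig(reduceCfg$kPerClass,
                              reduceCfg$pixelsPerCentroid,
                              deriveSeed(seed, "reduce-final"))))
  report <- runFold(finalTrain, test, sel$subset, svmCfg)
  reference <- runFold(finalTrain, test, NULL, svmCfg)
  list(heldOut = fold$heldOut, subset = sel$subset,
       fitness = sel$fitness, trace = sel$trace,
       report = report, reference = reference)
}

#' PF2: per-fold GA/PSO band selection with coincidence aggregation
#'
#' For every leave-one-patient-out fold: reduces the training patients'
#' pixels to balanced prototypes, builds the penalized wrapper fitness,
#' runs the chosen optimizer, then retrains on the selected bands and
#' scores the held-out patient (a full-band reference report is produced
#' alongside). Per-fold band sets are aggregated into coincidence levels.
#'
#' By default the wrapper fitness is scored on an inner validation patient
#' drawn from the training patients, so the held-out test patient never
#' influences band selection; \code{paperLiteral = TRUE} scores candidate
#' subsets directly on the test patient instead (the literal protocol of
#' the original description, which leaks test data into selection).
#'
#' @param data A normalized \linkS4class{LabeledDataset}.
#' @param method "ga" or "pso".
#' @param fitness "fom_p" or "oa_p".
#' @param optimCfg Named list of optimizer settings overriding the
#'   \code{\link{gaConfig}}/\code{\link{psoConfig}} defaults.
#' @param reduceCfg A \code{\link{reductionConfig}}.
#' @param svmCfg An \code{\link{svmConfig}}.
#' @param paperLiteral Score candidate subsets on the test patient.
#' @param seed Global seed; stage seeds are derived from it.
#' @param folds Optional integer vector restricting which folds to run.
#' @param evaluateCoincidence Re-run the evaluation per coincidence level.
#' @param outDir Optional artifact directory (bands.json, metrics.json).
#' @return List: \code{folds} (per-fold selection + reports),
#'   \code{levels} (\linkS4class{CoincidenceLevels}), \code{levelReports}
#'   (if requested), \code{summary}, \code{referenceSummary}.
#' @export
runPF2 <- function(data, method = c("ga", "pso"),
                   fitness = c("fom_p", "oa_p"), optimCfg = list(),
                   reduceCfg = reductionConfig(), svmCfg = svmConfig(),
                   paperLiteral = FALSE, seed = 1L, folds = NULL,
                   evaluateCoincidence = FALSE, outDir = NULL) {
  method <- match.arg(method)
  fitness <- match.arg(fitness)
  plan <- makeFolds(data)
  if (!is.null(folds)) plan <- plan[folds]
  res <- lapply(plan, function(f)
    .pf2Fold(data, f, method, fitness, optimCfg, reduceCfg, svmCfg,
             paperLiteral, seed))
  levels <- computeLevels(lapply(res, `[[`, "subset"))
  out <- list(
    folds = res, levels = levels,
    summary = aggregateReports(lapply(res, `[[`, "report")),
    referenceSummary = aggregateReports(lapply(res, `[[`, "reference")))
  if (evaluateCoincidence) {
    harness <- function(subset)
      evaluateLOPO(data, bands = subset, svmCfg = svmCfg,
                   reduceCfg = reduceCfg)$summary
    out$levelReports <- evaluateLevels(levels, harness)
  }
  .writeJSON(lapply(res, function(f) list(
    held_out = f$heldOut, bands = f$subset@indices,
    wavelengths_nm = if (length(f$subset@wavelengths))
      round(f$subset@wavelengths[f$subset@indices], 2) else NULL,
    fitness = f$fitness, trace = f$trace)), outDir, "bands.json")
  .writeJSON(lapply(res, function(f) .reportAsList(f$report)),
             outDir, "metrics.json")
  out
}

#' PF3: ant-colony band ranking with top-k evaluation
#'
#' For every fold: reduces the training patients' pixels, ranks all bands
#' with the ant-colony procedure, and evaluates the top 20/40/60/80/100
#' (configurable) ranked bands on the held-out patient.
#'
#' @param data A normalized \linkS4class{LabeledDataset}.
#' @param acoCfg An \code{\link{acoConfig}}.
#' @param reduceCfg A \code{\link{reductionConfig}}.
#' @param svmCfg An \code{\link{svmConfig}}.
#' @param seed Global seed.
#' @param folds Optional integer vector restricting which folds to run.
#' @param outDir Optional artifact directory (pf3.json).
#' @return List: per-fold \code{ranking} and per-k
#'   \linkS4class{MetricsReport}s, plus a per-k aggregated summary.
#' @export
runPF3 <- function(data, acoCfg = acoConfig(),
                   reduceCfg = reductionConfig(), svmCfg = svmConfig(),
                   seed = 1L, folds = NULL, outDir = NULL) {
  plan <- makeFolds(data)
  if (!is.null(folds)) plan <- plan[folds]
  pids <- patientIds(data)
  topK <- acoCfg$topK[acoCfg$topK <= nBands(data)]
  res <- lapply(plan, function(f) {
    trainAll <- data[, pids %in% f$trainPatients]
    test <- data[, pids == f$heldOut]
    red <- suppressWarnings(reduceTrainingSet(
      trainAll, reductionConfig(reduceCfg$kPerClass,
                                reduceCfg$pixelsPerCentroid,
                                deriveSeed(seed, "reduce"))))
    acoCfg$seed <- deriveSeed(seed, paste0("aco", f$heldOut))
    ranking <- acoRank(red, do.call(acoConfig, unclass(acoCfg)), svmCfg)
    perK <- acoTopkEvaluate(ranking, topK, function(idx)
      runFold(red, test, idx, svmCfg))
    list(heldOut = f$heldOut, ranking = ranking, perK = perK)
  })
  summary <- lapply(paste0("k", topK), function(kn)
    aggregateReports(lapply(res, function(f) f$perK[[kn]])))
  names(summary) <- paste0("k", topK)
  .writeJSON(lapply(res, function(f)
    list(held_out = f$heldOut, ranking = f$ranking)), outDir, "pf3.json")
  list(folds = res, summary = summary)
}
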