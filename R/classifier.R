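#' @include AllClasses.R
NULL

#' SVM configuration
#'
#' Linear kernel with cost 1 by default: fast enough to sit inside wrapper
#' band-selection loops while separating the (near-linear) normalized
#' tissue spectra well. Spectra are already normalized to [0, 1], so the
#' classifier applies no further feature scaling.
#'
#' @param kernel e1071 kernel name (default "linear").
#' @param cost Soft-margin cost C.
#' @param gamma Kernel gamma (NULL = e1071 default, RBF only).
#' @param seed Seed for any stochastic classifier component.
#' @return A classed settings list.
#' @export
svmConfig <- function(kernel = "linear", cost = 1, gamma = NULL, seed = 1L) {
  structure(list(kernel = kernel, cost = cost, gamma = gamma,
                 seed = as.integer(seed)),
            class = "svmConfig")
}

.bandIdx <- function(bands, nb) {
  idx <- if (is(bands, "BandSubset")) bands@indices else as.integer(bands)
  if (!length(idx)) stop("band subset must be nonempty")
  if (any(idx < 1L | idx > nb)) stop("band index out of range")
  idx
}

#' Train a multiclass SVM on a labeled dataset
#'
#' @param train A \linkS4class{LabeledDataset} (normalized spectra).
#' @param bands \linkS4class{BandSubset} or integer indices (NULL = all).
#' @param cfg An \code{\link{svmConfig}}.
#' @return Fitted \code{e1071::svm} model (one-vs-one multiclass) with the
#'   band indices attached as attribute \code{"bands"}.
#' @export
trainSVM <- function(train, bands = NULL, cfg = svmConfig()) {
  idx <- if (is.null(bands)) seq_len(nBands(train))
         else .bandIdx(bands, nBands(train))
  X <- t(spectra(train)[idx, , drop = FALSE])
  y <- factor(pixelLabels(train))
  args <- list(x = X, y = y, kernel = cfg$kernel, cost = cfg$cost,
               scale = FALSE)
  if (!is.null(cfg$gamma)) args$gamma <- cfg$gamma
  model <- withr::with_seed(cfg$seed, do.call(e1071::svm, args))
  attr(model, "bands") <- idx
  model
}

.predictLabels <- function(model, M) {
  idx <- attr(model, "bands")
  as.integer(as.character(predict(model, t(M[idx, , drop = FALSE]))))
}

#' Build the leave-one-patient-out fold plan
#'
#' One fold per distinct patient id; the fold's training set is every other
#' patient. Generalization is therefore always measured on a patient unseen
#' during training.
#'
#' @param data A \linkS4class{LabeledDataset} with >= 2 patients.
#' @return List of folds, each \code{list(heldOut, trainPatients)}.
#' @export
makeFolds <- function(data) {
  pids <- sort(unique(patientIds(data)))
  if (length(pids) < 2L)
    stop("leave-one-patient-out requires at least 2 patients")
  lapply(pids, function(p)
    list(heldOut = p, trainPatients = setdiff(pids, p)))
}

#' Train on one fold and evaluate on the held-out patient
#'
#' @param train,test \linkS4class{LabeledDataset}s with disjoint patients.
#' @param bands \linkS4class{BandSubset} or indices (NULL = all bands).
#' @param cfg An \code{\link{svmConfig}}.
#' @return A \linkS4class{MetricsReport} over the four classes.
#' @export
runFold <- function(train, test, bands = NULL, cfg = svmConfig()) {
  if (length(intersect(unique(patientIds(train)),
                       unique(patientIds(test)))))
    stop("train and test share patients (leakage)")
  model <- trainSVM(train, bands, cfg)
  pred <- .predictLabels(model, spectra(test))
  metricsReport(confusionCounts(pixelLabels(test), pred, 4L))
}

#' Leave-one-patient-out evaluation
#'
#' For each fold: optionally reduce the training patients' pixels to
#' balanced prototypes (the reduction never sees the held-out patient),
#' train the SVM on the given bands, and score the held-out patient.
#'
#' @param data A normalized \linkS4class{LabeledDataset}.
#' @param bands \linkS4class{BandSubset} or indices (NULL = all bands).
#' @param svmCfg An \code{\link{svmConfig}}.
#' @param reduceCfg Optional \code{\link{reductionConfig}}; NULL trains on
#'   all training pixels.
#' @param folds Optional integer vector restricting which folds to run.
#' @return List with \code{folds} (per-fold \linkS4class{MetricsReport}),
#'   \code{heldOut} (patient per fold) and \code{summary}
#'   (\code{\link{aggregateReports}} output).
#' @export
evaluateLOPO <- function(data, bands = NULL, svmCfg = svmConfig(),
                         reduceCfg = NULL, folds = NULL) {
  plan <- makeFolds(data)
  if (!is.null(folds)) plan <- plan[folds]
  pids <- patientIds(data)
  reports <- lapply(plan, function(f) {
    train <- data[, pids %in% f$trainPatients]
    test <- data[, pids == f$heldOut]
    if (!is.null(reduceCfg)) {
      train <- suppressWarnings(reduceTrainingSet(train, reduceCfg))
      stopifnot(!f$heldOut %in% patientIds(train))
    }
    runFold(train, test, bands, svmCfg)
  })
  list(folds = reports,
       heldOut = vapply(plan, `[[`, character(1), "heldOut"),
       summary = aggregateReports(reports))
}

#' Fixed class palette for classification maps
#'
#' Green, red, blue and black for normal, tumor, hypervascularized and
#' background tissue respectively.
#'
#' @return Named character vector of colors.
#' @export
classPalette <- function() {
  c(normal = "green", tumor = "red", hypervascularized = "blue",
    background = "black")
}

#' Classify every pixel of a cube and render a classification map
#'
#' All pixels (labeled or not) are classified; the map uses the fixed
#' green/red/blue/black palette. Optionally writes an RGB PNG.
#'
#' @param cube A normalized \linkS4class{HSCube}.
#' @param model SVM from \code{\link{trainSVM}} (trained on this grid).
#' @param file Optional output PNG path.
#' @return A \linkS4class{ClassificationMap}.
#' @export
renderMap <- function(cube, model, file = NULL) {
  d <- dim(cube@values)
  if (max(attr(model, "bands")) > d[3])
    stop("model bands do not fit the cube grid")
  M <- t(matrix(cube@values, d[1] * d[2], d[3]))
  pred <- .predictLabels(model, M)
  map <- new("ClassificationMap",
             labels = matrix(pred, d[1], d[2]),
             palette = classPalette())
  if (!is.null(file)) {
    rgb <- grDevices::col2rgb(classPalette()) / 255
    img <- array(0, dim = c(d[1], d[2], 3))
    for (ch in 1:3)
      img[, , ch] <- matrix(rgb[ch, pred + 1L], d[1], d[2])
    png::writePNG(img, file)
  }
  map
}
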