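#' @import methods
#' @importFrom stats kmeans predict runif rnorm sd var cor quantile
#' @importFrom utils combn head modifyList
#' @importFrom grDevices col2rgb
#' @importClassesFrom SummarizedExperiment SummarizedExperiment
#' @importFrom SummarizedExperiment SummarizedExperiment assay colData rowData
NULL

## Class codes used throughout: 0 normal, 1 tumor, 2 hypervascularized,
## 3 background, 255 unlabeled (ground-truth maps only).

#' Tissue class codes
#'
#' Integer codes used for the four tissue classes plus the unlabeled code
#' used in ground-truth maps.
#'
#' @return Named integer vector of class codes.
#' @examples
#' tissueClasses()
#' @export
tissueClasses <- function() {
  c(normal = 0L, tumor = 1L, hypervascularized = 2L, background = 3L,
    unlabeled = 255L)
}

.CLASS_NAMES <- c("normal", "tumor", "hypervascularized", "background")
.UNLABELED <- 255L

#' SpectralGrid: the wavelength axis of a hyperspectral acquisition
#'
#' Holds the ordered band-center wavelengths (nm). The grid defines band
#' identity for every downstream object (cubes, datasets, band subsets).
#'
#' @slot wavelengths Numeric vector of strictly increasing band-center
#'   wavelengths in nanometers.
#' @export
setClass("SpectralGrid", representation(wavelengths = "numeric"))

setValidity("SpectralGrid", function(object) {
  wl <- object@wavelengths
  if (length(wl) && any(!is.finite(wl)))
    return("wavelengths must be finite")
  if (length(wl) > 1 && any(diff(wl) <= 0))
    return("wavelengths must be strictly increasing")
  TRUE
})

#' Construct a SpectralGrid
#'
#' @param wavelengths Strictly increasing numeric vector of band-center
#'   wavelengths (nm).
#' @return A \linkS4class{SpectralGrid}.
#' @examples
#' g <- spectralGrid(seq(440, 902, length.out = 128))
#' nBands(g)
#' @export
spectralGrid <- function(wavelengths) {
  new("SpectralGrid", wavelengths = as.numeric(wavelengths))
}

#' Default operating grid: 440-902 nm, 128 bands
#'
#' The pipeline's standard operating point after extreme-band removal and
#' decimation (3.61 nm sampling interval).
#'
#' @return A \linkS4class{SpectralGrid} with 128 bands.
#' @export
defaultGrid <- function() {
  spectralGrid(seq(440, 902, length.out = 128))
}

#' HSCube: a hyperspectral reflectance cube
#'
#' A rows x cols x bands reflectance array together with its wavelength grid
#' and acquisition identifiers. Flags record whether radiometric calibration
#' and per-pixel normalization have been applied.
#'
#' @slot values 3-D numeric array (rows x cols x bands).
#' @slot grid \linkS4class{SpectralGrid} matching the third dimension.
#' @slot patientId,imageId Character identifiers.
#' @slot calibrated,normalized Logical processing flags.
#' @export
setClass("HSCube", representation(
  values = "array", grid = "SpectralGrid",
  patientId = "character", imageId = "character",
  calibrated = "logical", normalized = "logical"))

setValidity("HSCube", function(object) {
  d <- dim(object@values)
  if (length(d) != 3) return("values must be a 3-D array")
  if (d[3] != length(object@grid@wavelengths))
    return("third dimension must equal the number of grid bands")
  TRUE
})

#' Construct an HSCube
#'
#' @param values rows x cols x bands numeric array of reflectance.
#' @param grid \linkS4class{SpectralGrid}; band count must match dim 3.
#' @param patientId,imageId Identifiers attached to the acquisition.
#' @param calibrated,normalized Processing flags.
#' @return An \linkS4class{HSCube}.
#' @export
hsCube <- function(values, grid, patientId = "P000", imageId = "im00",
                   calibrated = FALSE, normalized = FALSE) {
  new("HSCube", values = values, grid = grid, patientId = patientId,
      imageId = imageId, calibrated = calibrated, normalized = normalized)
}

#' LabeledDataset: labeled pixel spectra
#'
#' A \linkS4class{SummarizedExperiment} with bands as rows and pixels as
#' columns. The single assay \code{"spectra"} holds reflectance; per-pixel
#' metadata (\code{label}, \code{patient_id}, \code{image_id}) lives in
#' \code{colData} and the wavelength axis in \code{rowData}.
#'
#' @export
setClass("LabeledDataset", contains = "SummarizedExperiment")

setValidity("LabeledDataset", function(object) {
  cd <- SummarizedExperiment::colData(object)
  need <- c("label", "patient_id", "image_id")
  if (!all(need %in% colnames(cd)))
    return(paste("colData must contain", paste(need, collapse = ", ")))
  if (ncol(object) && !all(cd$label %in% 0:3))
    return("labels must be class codes 0..3")
  rd <- SummarizedExperiment::rowData(object)
  if (!"wavelength" %in% colnames(rd))
    return("rowData must contain a wavelength column")
  wl <- rd$wavelength
  if (length(wl) > 1 && any(diff(wl) <= 0))
    return("wavelengths must be strictly increasing")
  TRUE
})

#' Construct a LabeledDataset
#'
#' @param spectra bands x pixels numeric matrix.
#' @param labels Integer class codes (0..3), one per pixel.
#' @param patientIds Character vector, one per pixel.
#' @param imageIds Character vector, one per pixel (default patientIds).
#' @param grid \linkS4class{SpectralGrid} for the rows.
#' @return A \linkS4class{LabeledDataset}.
#' @export
labeledDataset <- function(spectra, labels, patientIds,
                           imageIds = patientIds, grid) {
  spectra <- as.matrix(spectra)
  se <- SummarizedExperiment::SummarizedExperiment(
    assays = list(spectra = spectra),
    rowData = S4Vectors::DataFrame(wavelength = grid@wavelengths),
    colData = S4Vectors::DataFrame(
      label = as.integer(labels),
      patient_id = as.character(patientIds),
      image_id = as.character(imageIds)))
  new("LabeledDataset", se)
}

#' ClassSignatureModel: parametric spectral signature of one class
#'
#' Mean and standard-deviation spectra over a grid, plus the magnitude of
#' smooth inter-patient mean shifts.
#'
#' @slot classId One of "normal", "tumor", "hypervascularized", "background".
#' @slot meanSpectrum,stdevSpectrum Numeric vectors over the grid bands
#'   (reflectance, 0-100 scale before normalization).
#' @slot patientOffsetSd Scalar magnitude of per-patient offsets.
#' @export
setClass("ClassSignatureModel", representation(
  classId = "character", meanSpectrum = "numeric", stdevSpectrum = "numeric",
  patientOffsetSd = "numeric"))

setValidity("ClassSignatureModel", function(object) {
  if (!object@classId %in% .CLASS_NAMES) return("unknown classId")
  if (length(object@meanSpectrum) != length(object@stdevSpectrum))
    return("mean and stdev spectra must have equal length")
  if (any(object@stdevSpectrum < 0)) return("stdev must be >= 0")
  if (object@patientOffsetSd < 0) return("patientOffsetSd must be >= 0")
  TRUE
})

#' SyntheticSceneSpec: parameters of a synthetic acquisition campaign
#'
#' @slot grid Target \linkS4class{SpectralGrid}.
#' @slot nPatients Number of synthetic patients (>= 2 so that
#'   leave-one-patient-out folds exist).
#' @slot pixelsPerClassPerPatient Labeled pixels generated per class per
#'   patient.
#' @slot glareFraction Proportion of cube pixels replaced by near-saturated
#'   specular glare and marked unlabeled.
#' @slot seed Integer seed making every draw reproducible.
#' @export
setClass("SyntheticSceneSpec", representation(
  grid = "SpectralGrid", nPatients = "integer",
  pixelsPerClassPerPatient = "integer", glareFraction = "numeric",
  seed = "integer"))

setValidity("SyntheticSceneSpec", function(object) {
  if (object@nPatients < 2L) return("nPatients must be >= 2")
  if (object@pixelsPerClassPerPatient < 1L)
    return("pixelsPerClassPerPatient must be > 0")
  if (object@glareFraction < 0 || object@glareFraction >= 1)
    return("glareFraction must be in [0, 1)")
  TRUE
})

#' Construct a SyntheticSceneSpec
#'
#' Defaults describe the package's standard study conditions: four patients,
#' 500 labeled pixels per class per patient on the 128-band 440-902 nm grid,
#' with 2\% glare in generated cubes.
#'
#' @param grid \linkS4class{SpectralGrid} (default \code{defaultGrid()}).
#' @param nPatients Number of patients (>= 2).
#' @param pixelsPerClassPerPatient Labeled pixels per class per patient.
#' @param glareFraction Glare proportion in generated cubes, in [0, 1).
#' @param seed Integer seed.
#' @return A \linkS4class{SyntheticSceneSpec}.
#' @export
syntheticSceneSpec <- function(grid = defaultGrid(), nPatients = 4L,
                               pixelsPerClassPerPatient = 500L,
                               glareFraction = 0.02, seed = 1L) {
  new("SyntheticSceneSpec", grid = grid, nPatients = as.integer(nPatients),
      pixelsPerClassPerPatient = as.integer(pixelsPerClassPerPatient),
      glareFraction = as.numeric(glareFraction), seed = as.integer(seed))
}

#' BandSubset: a selected set of bands over a grid
#'
#' @slot indices Sorted unique 1-based band indices.
#' @slot nTotal Total band count of the underlying grid.
#' @slot wavelengths Band-center wavelengths of the full grid (length
#'   \code{nTotal}), or empty when the subset is detached from a grid.
#' @export
setClass("BandSubset", representation(
  indices = "integer", nTotal = "integer", wavelengths = "numeric"))

setValidity("BandSubset", function(object) {
  idx <- object@indices
  if (!length(idx)) return("band subset must be nonempty")
  if (anyDuplicated(idx)) return("band indices must be unique")
  if (any(idx < 1L) || any(idx > object@nTotal))
    return("band indices out of range")
  if (is.unsorted(idx)) return("band indices must be sorted")
  if (length(object@wavelengths) &&
      length(object@wavelengths) != object@nTotal)
    return("wavelengths must have length nTotal (or 0)")
  TRUE
})

#' Construct a BandSubset
#'
#' @param indices 1-based band indices (deduplicated and sorted).
#' @param nTotal Total number of bands in the grid.
#' @param grid Optional \linkS4class{SpectralGrid}; when given, supplies
#'   \code{nTotal} and the wavelength axis.
#' @return A \linkS4class{BandSubset}.
#' @export
bandSubset <- function(indices, nTotal = NULL, grid = NULL) {
  idx <- sort(unique(as.integer(indices)))
  wl <- numeric(0)
  if (!is.null(grid)) {
    wl <- grid@wavelengths
    nTotal <- length(wl)
  }
  new("BandSubset", indices = idx, nTotal = as.integer(nTotal),
      wavelengths = wl)
}

#' ConfusionCounts: multiclass confusion matrix
#'
#' @slot table n x n integer matrix, rows = true class, cols = predicted.
#' @slot classes Integer class codes labelling rows/cols.
#' @export
setClass("ConfusionCounts",
         representation(table = "matrix", classes = "integer"))

setValidity("ConfusionCounts", function(object) {
  if (nrow(object@table) != ncol(object@table))
    return("confusion table must be square")
  if (length(object@classes) != nrow(object@table))
    return("classes must label the table dimensions")
  if (any(object@table < 0)) return("counts must be >= 0")
  TRUE
})

#' FitnessValue: penalized fitness of a band subset
#'
#' Score to be minimized: \code{(1 - base) * (1 + lambda/lambdaMax)} where
#' \code{base} is OA or FoM, \code{lambda} the number of selected bands and
#' \code{lambdaMax} the total band count.
#'
#' @slot value Nonnegative score (lower is better).
#' @slot baseMetric "oa_p" or "fom_p".
#' @slot nSelected,nTotal Band counts lambda and lambdaMax.
#' @export
setClass("FitnessValue", representation(
  value = "numeric", baseMetric = "character",
  nSelected = "integer", nTotal = "integer"))

setValidity("FitnessValue", function(object) {
  if (object@value < 0) return("fitness value must be >= 0")
  if (object@nSelected > object@nTotal)
    return("nSelected must be <= nTotal")
  if (!object@baseMetric %in% c("oa_p", "fom_p"))
    return("baseMetric must be 'oa_p' or 'fom_p'")
  TRUE
})

#' MetricsReport: per-fold classification scores
#'
#' @slot confusion \linkS4class{ConfusionCounts}.
#' @slot oa Overall accuracy.
#' @slot sensitivity,specificity,mcc,mccNorm Named per-class vectors
#'   (one-vs-rest); NA where a denominator is undefined.
#' @slot fom Pairwise balanced figure of merit over per-class accuracies.
#' @export
setClass("MetricsReport", representation(
  confusion = "ConfusionCounts", oa = "numeric",
  sensitivity = "numeric", specificity = "numeric",
  mcc = "numeric", mccNorm = "numeric", fom = "numeric"))

#' ClassificationMap: predicted class codes over a cube's spatial grid
#'
#' @slot labels rows x cols integer matrix of predicted class codes (0..3).
#' @slot palette Named class -> color map (green/red/blue/black for
#'   normal/tumor/hypervascularized/background).
#' @export
setClass("ClassificationMap",
         representation(labels = "matrix", palette = "character"))

#' CoincidenceLevels: bands selected in at least i of the per-fold runs
#'
#' Level \code{L_i} contains the bands appearing in at least \code{i} of the
#' per-fold band subsets; levels are nested, \code{L_{i+1}} a subset of
#' \code{L_i}. Levels with no bands are stored as NULL.
#'
#' @slot levels List of \linkS4class{BandSubset} (or NULL), element i = L_i.
#' @slot nFolds Number of per-fold subsets aggregated.
#' @export
setClass("CoincidenceLevels",
         representation(levels = "list", nFolds = "integer"))

setValidity("CoincidenceLevels", function(object) {
  prev <- NULL
  for (lv in object@levels) {
    if (is.null(lv)) next
    if (!is.null(prev) && !all(lv@indices %in% prev@indices))
      return("levels must be nested (L_{i+1} subset of L_i)")
    prev <- lv
  }
  TRUE
})
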