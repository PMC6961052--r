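#' @include AllGenerics.R
NULL

#' @rdname spectralGrid
#' @export
setMethod("wavelengths", "SpectralGrid", function(x) x@wavelengths)

#' @rdname spectralGrid
#' @export
setMethod("nBands", "SpectralGrid", function(x) length(x@wavelengths))

#' @rdname spectralGrid
#' @export
setMethod("lambdaMin", "SpectralGrid", function(x) x@wavelengths[1L])

#' @rdname spectralGrid
#' @export
setMethod("lambdaMax", "SpectralGrid",
          function(x) x@wavelengths[length(x@wavelengths)])

#' @rdname sGrid
#' @export
setMethod("sGrid", "HSCube", function(x) x@grid)

#' @rdname sGrid
#' @export
setMethod("sGrid", "LabeledDataset", function(x)
  spectralGrid(SummarizedExperiment::rowData(x)$wavelength))

#' @rdname spectralGrid
#' @export
setMethod("wavelengths", "HSCube", function(x) x@grid@wavelengths)

#' @rdname spectralGrid
#' @export
setMethod("nBands", "HSCube", function(x) length(x@grid@wavelengths))

#' @rdname spectralGrid
#' @export
setMethod("wavelengths", "LabeledDataset",
          function(x) SummarizedExperiment::rowData(x)$wavelength)

#' @rdname spectralGrid
#' @export
setMethod("nBands", "LabeledDataset", function(x) nrow(x))

#' @rdname spectra
#' @export
setMethod("spectra", "LabeledDataset",
          function(x) SummarizedExperiment::assay(x, "spectra"))

#' @rdname pixelLabels
#' @export
setMethod("pixelLabels", "LabeledDataset",
          function(x) SummarizedExperiment::colData(x)$label)

#' @rdname patientIds
#' @export
setMethod("patientIds", "LabeledDataset",
          function(x) SummarizedExperiment::colData(x)$patient_id)

#' @rdname imageIds
#' @export
setMethod("imageIds", "LabeledDataset",
          function(x) SummarizedExperiment::colData(x)$image_id)

#' Number of pixels in a LabeledDataset
#' @param x A LabeledDataset.
#' @export
nPixels <- function(x) ncol(x)

#' @rdname bandIndices
#' @export
setMethod("bandIndices", "BandSubset", function(x) x@indices)

#' @rdname spectralGrid
#' @export
setMethod("nBands", "BandSubset", function(x) length(x@indices))

#' @rdname spectralGrid
#' @export
setMethod("wavelengths", "BandSubset", function(x) {
  if (!length(x@wavelengths)) stop("band subset carries no wavelength axis")
  x@wavelengths[x@indices]
})

setMethod("show", "SpectralGrid", function(object) {
  wl <- object@wavelengths
  cat(sprintf("SpectralGrid: %d bands, %.2f-%.2f nm (sampling interval %.2f nm)\n",
              length(wl), wl[1L], wl[length(wl)],
              (wl[length(wl)] - wl[1L]) / length(wl)))
})

setMethod("show", "HSCube", function(object) {
  d <- dim(object@values)
  cat(sprintf("HSCube %s/%s: %d x %d pixels, %d bands [%s%s]\n",
              object@patientId, object@imageId, d[1], d[2], d[3],
              if (object@calibrated) "calibrated" else "raw",
              if (object@normalized) ", normalized" else ""))
})

setMethod("show", "LabeledDataset", function(object) {
  cat(sprintf("LabeledDataset: %d pixels x %d bands, %d patients\n",
              ncol(object), nrow(object),
              length(unique(patientIds(object)))))
  tab <- table(factor(pixelLabels(object), levels = 0:3,
                      labels = .CLASS_NAMES))
  print(tab)
})

setMethod("show", "BandSubset", function(object) {
  cat(sprintf("BandSubset: %d of %d bands\n",
              length(object@indices), object@nTotal))
  if (length(object@wavelengths))
    cat(sprintf("  wavelengths (nm): %s\n",
                paste(sprintf("%.2f", object@wavelengths[object@indices]),
                      collapse = ", ")))
})

setMethod("show", "ClassSignatureModel", function(object) {
  cat(sprintf("ClassSignatureModel '%s': %d bands, mean range %.1f-%.1f\n",
              object@classId, length(object@meanSpectrum),
              min(object@meanSpectrum), max(object@meanSpectrum)))
})

setMethod("show", "MetricsReport", function(object) {
  cat(sprintf("MetricsReport: OA %.3f, FoM %.3f\n", object@oa, object@fom))
  m <- rbind(sensitivity = object@sensitivity,
             specificity = object@specificity,
             mccNorm = object@mccNorm)
  print(round(m, 3))
})

setMethod("show", "CoincidenceLevels", function(object) {
  cat(sprintf("CoincidenceLevels over %d folds:\n", object@nFolds))
  for (i in seq_along(object@levels)) {
    lv <- object@levels[[i]]
    cat(sprintf("  L%d: %s bands\n", i,
                if (is.null(lv)) "0" else length(lv@indices)))
  }
})

#' Derive a stage-specific seed from a global seed
#'
#' Every stochastic stage of the pipeline draws its own seed from the global
#' seed plus the stage name, so that stages are independently reproducible.
#'
#' @param seed Global integer seed.
#' @param stage Character stage name.
#' @return Integer seed in [0, 2^31).
#' @export
deriveSeed <- function(seed, stage) {
  v <- utf8ToInt(stage)
  h <- sum(v * seq_along(v))
  as.integer((as.numeric(seed) %% 65536 * 7919 + h * 131) %% 2147483647)
}
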