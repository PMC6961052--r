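#' @include AllClasses.R
NULL

#' @rdname spectralGrid
#' @param x A SpectralGrid, HSCube, LabeledDataset or BandSubset.
#' @export
setGeneric("wavelengths", function(x) standardGeneric("wavelengths"))

#' @rdname spectralGrid
#' @export
setGeneric("nBands", function(x) standardGeneric("nBands"))

#' @rdname spectralGrid
#' @export
setGeneric("lambdaMin", function(x) standardGeneric("lambdaMin"))

#' @rdname spectralGrid
#' @export
setGeneric("lambdaMax", function(x) standardGeneric("lambdaMax"))

#' Extract the SpectralGrid of an object
#' @param x An HSCube or LabeledDataset.
#' @return A \linkS4class{SpectralGrid}.
#' @export
setGeneric("sGrid", function(x) standardGeneric("sGrid"))

#' Pixel spectra of a LabeledDataset
#' @param x A LabeledDataset.
#' @return bands x pixels numeric matrix.
#' @export
setGeneric("spectra", function(x) standardGeneric("spectra"))

#' Per-pixel class labels
#' @param x A LabeledDataset.
#' @export
setGeneric("pixelLabels", function(x) standardGeneric("pixelLabels"))

#' Per-pixel patient identifiers
#' @param x A LabeledDataset.
#' @export
setGeneric("patientIds", function(x) standardGeneric("patientIds"))

#' Per-pixel image identifiers
#' @param x A LabeledDataset.
#' @export
setGeneric("imageIds", function(x) standardGeneric("imageIds"))

#' Band indices of a BandSubset
#' @param x A BandSubset.
#' @return Sorted integer vector of 1-based band indices.
#' @export
setGeneric("bandIndices", function(x) standardGeneric("bandIndices"))

#' Remove noisy extreme bands outside a kept wavelength window
#'
#' Retains bands with \code{keepMin <= wavelength <= keepMax} (default the
#' 440-902 nm operating bandwidth that discards the low-sensor-performance
#' extremes) and updates the grid.
#'
#' @param x An HSCube or LabeledDataset.
#' @param keepMin,keepMax Window bounds in nm.
#' @return Object of the same class restricted to the kept bands.
#' @export
setGeneric("removeExtremeBands",
           function(x, keepMin = 440, keepMax = 902)
             standardGeneric("removeExtremeBands"))

#' Smooth spectra with a centered moving average
#'
#' Reduces per-band sensor noise with a moving average along the spectral
#' axis; edge bands use shrinking (truncated) windows so the band count is
#' preserved.
#'
#' @param x An HSCube or LabeledDataset.
#' @param window Odd window length in bands (default 5).
#' @return Smoothed object of the same class.
#' @export
setGeneric("smoothSpectra",
           function(x, window = 5L) standardGeneric("smoothSpectra"))

#' Min-max normalize each pixel's spectrum to [0, 1]
#'
#' Per pixel, subtracts the pixel minimum and divides by the pixel range,
#' homogenizing reflectance levels across the non-uniform tissue surface.
#' Pixels with zero range (flat spectra, e.g. dead or glare pixels) are set
#' to all zeros with a warning.
#'
#' @param x An HSCube or LabeledDataset.
#' @return Normalized object of the same class.
#' @export
setGeneric("normalizePixels", function(x) standardGeneric("normalizePixels"))

#' Decimate the spectral axis to a target band count
#'
#' Emulates a coarser sampling interval: places \code{nBands} target
#' wavelengths at the midpoints of equal intervals spanning the grid and
#' keeps, for each target, the nearest existing band (ties resolved toward
#' the lower index; no band kept twice).
#'
#' @param x An HSCube or LabeledDataset.
#' @param nBands Target band count (1..current band count).
#' @return Object of the same class on the decimated grid.
#' @export
setGeneric("decimateBands",
           function(x, nBands) standardGeneric("decimateBands"))
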