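#' @include AllGenerics.R
NULL

#' Radiometric calibration against white and dark references
#'
#' Converts raw sensor counts to percent reflectance using the element-wise
#' rule \code{C = 100 * (R - D) / (W - D)}, where W is the image of a
#' standard white tile under the operating illumination and D the closed
#' shutter (dark current) image.
#'
#' @param raw Uncalibrated \linkS4class{HSCube} of sensor counts.
#' @param refs A \code{\link{referencePair}} with matching dimensions.
#' @return Calibrated \linkS4class{HSCube} (0-100 scale, flag set).
#' @examples
#' g <- spectralGrid(c(500, 600))
#' raw <- hsCube(array(55, c(2, 2, 2)), g)
#' refs <- referencePair(array(110, c(2, 2, 2)), array(10, c(2, 2, 2)))
#' calibrate(raw, refs)@values[1, 1, ]  # 45 45
#' @export
calibrate <- function(raw, refs) {
  if (raw@calibrated) stop("cube is already calibrated")
  W <- refs$white; D <- refs$dark
  if (!all(dim(W) == dim(raw@values)))
    stop("reference dimensions do not match the cube")
  denom <- W - D
  if (any(denom == 0)) stop("degenerate reference (white == dark)")
  out <- raw
  out@values <- 100 * (raw@values - D) / denom
  out@calibrated <- TRUE
  out
}

#' White/dark reference image pair
#'
#' @param white,dark Arrays of raw counts with the raw cube's dimensions.
#'   \code{white} must exceed \code{dark} everywhere.
#' @return List with elements \code{white} and \code{dark}.
#' @export
referencePair <- function(white, dark) {
  if (!all(dim(white) == dim(dark)))
    stop("white and dark references must have identical dimensions")
  if (any(white <= dark))
    stop("white reference must exceed dark reference everywhere")
  list(white = white, dark = dark)
}

#' Spectral sampling interval
#'
#' Distance in nm between adjacent sampling points for a sensor covering
#' \code{lambdaMin..lambdaMax} with \code{nBands} bands:
#' \code{(lambdaMax - lambdaMin) / nBands}.
#'
#' @param lambdaMin,lambdaMax Spectral range bounds in nm.
#' @param nBands Number of spectral bands (>= 1).
#' @return Sampling interval in nm.
#' @examples
#' samplingInterval(440, 902, 128)  # 3.609375 -> 3.61 nm
#' @export
samplingInterval <- function(lambdaMin, lambdaMax, nBands) {
  if (nBands < 1) stop("nBands must be >= 1")
  if (lambdaMax <= lambdaMin) stop("lambdaMax must exceed lambdaMin")
  (lambdaMax - lambdaMin) / nBands
}

## ---- shared band-axis helpers (matrices are bands x pixels) ----

.keepIdx <- function(wl, keepMin, keepMax) {
  if (keepMin >= keepMax) stop("keepMin must be < keepMax")
  idx <- which(wl >= keepMin & wl <= keepMax)
  if (!length(idx)) stop("no bands left in the kept range")
  idx
}

.smoothMat <- function(M, window) {
  window <- as.integer(window)
  nb <- nrow(M)
  if (window < 1L || window %% 2L == 0L)
    stop("window must be an odd positive band count")
  if (window > nb) stop("window exceeds the band count")
  if (window == 1L) return(M)
  half <- (window - 1L) %/% 2L
  out <- M
  for (i in seq_len(nb)) {
    lo <- max(1L, i - half); hi <- min(nb, i + half)
    out[i, ] <- colMeans(M[lo:hi, , drop = FALSE])
  }
  out
}

.normalizeMat <- function(M) {
  mins <- apply(M, 2, min)
  maxs <- apply(M, 2, max)
  rng <- maxs - mins
  flat <- rng == 0
  rng[flat] <- 1
  out <- sweep(sweep(M, 2, mins, "-"), 2, rng, "/")
  if (any(flat)) {
    out[, flat] <- 0
    warning(sprintf("%d constant pixel(s) set to zeros during normalization",
                    sum(flat)))
  }
  out
}

## Nearest existing band to each interval midpoint; ties to the lower
## index; a band is never selected twice (next-nearest free band is used).
.decimateIdx <- function(wl, nOut) {
  nb <- length(wl)
  nOut <- as.integer(nOut)
  if (nOut < 1L || nOut > nb)
    stop("nBands must be between 1 and the current band count")
  interval <- (wl[nb] - wl[1]) / nOut
  targets <- wl[1] + (seq_len(nOut) - 0.5) * interval
  taken <- logical(nb)
  sel <- integer(nOut)
  for (k in seq_len(nOut)) {
    d <- abs(wl - targets[k])
    d[taken] <- Inf
    sel[k] <- which.min(d)  # which.min takes the lower index on ties
    taken[sel[k]] <- TRUE
  }
  sort(sel)
}

## ---- HSCube methods ----

#' @rdname removeExtremeBands
#' @export
setMethod("removeExtremeBands", "HSCube", function(x, keepMin, keepMax) {
  idx <- .keepIdx(wavelengths(x), keepMin, keepMax)
  x@values <- x@values[, , idx, drop = FALSE]
  x@grid <- spectralGrid(wavelengths(x@grid)[idx])
  x
})

#' @rdname smoothSpectra
#' @export
setMethod("smoothSpectra", "HSCube", function(x, window) {
  d <- dim(x@values)
  M <- t(matrix(x@values, d[1] * d[2], d[3]))
  x@values <- array(t(.smoothMat(M, window)), dim = d)
  x
})

#' @rdname normalizePixels
#' @export
setMethod("normalizePixels", "HSCube", function(x) {
  if (!x@calibrated) stop("cube must be calibrated before normalization")
  d <- dim(x@values)
  M <- t(matrix(x@values, d[1] * d[2], d[3]))
  x@values <- array(t(.normalizeMat(M)), dim = d)
  x@normalized <- TRUE
  x
})

#' @rdname decimateBands
#' @export
setMethod("decimateBands", "HSCube", function(x, nBands) {
  idx <- .decimateIdx(wavelengths(x), nBands)
  x@values <- x@values[, , idx, drop = FALSE]
  x@grid <- spectralGrid(wavelengths(x@grid)[idx])
  x
})

## ---- LabeledDataset methods ----

.replaceSpectra <- function(x, M, wl = NULL) {
  if (is.null(wl)) wl <- SummarizedExperiment::rowData(x)$wavelength
  labeledDataset(M, pixelLabels(x), patientIds(x), imageIds(x),
                 spectralGrid(wl))
}

#' @rdname removeExtremeBands
#' @export
setMethod("removeExtremeBands", "LabeledDataset",
          function(x, keepMin, keepMax) {
  idx <- .keepIdx(wavelengths(x), keepMin, keepMax)
  x[idx, ]
})

#' @rdname smoothSpectra
#' @export
setMethod("smoothSpectra", "LabeledDataset", function(x, window) {
  .replaceSpectra(x, .smoothMat(spectra(x), window))
})

#' @rdname normalizePixels
#' @export
setMethod("normalizePixels", "LabeledDataset", function(x) {
  .replaceSpectra(x, .normalizeMat(spectra(x)))
})

#' @rdname decimateBands
#' @export
setMethod("decimateBands", "LabeledDataset", function(x, nBands) {
  idx <- .decimateIdx(wavelengths(x), nBands)
  x[idx, ]
})
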