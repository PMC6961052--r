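#' @include AllClasses.R
NULL

## Smooth base curves are sums of logistic ramps; hemoglobin absorption is
## modelled as Gaussian dips at 540/560/580 nm with class-specific depths.
## Oxygenated hemoglobin contributes the double valley at 540/580 nm and
## deoxygenated hemoglobin the single valley near 560 nm, so vessel-rich
## (hypervascularized) tissue shows the deepest valleys.

.logistic <- function(x) 1 / (1 + exp(-x))
.dip <- function(wl, center, width = 8) exp(-0.5 * ((wl - center) / width)^2)

.baseCurves <- function(wl) {
  list(
    normal = 18 + 45 * .logistic((wl - 580) / 40) -
      6 * .dip(wl, 540) - 4 * .dip(wl, 560) - 6 * .dip(wl, 580),
    tumor = 24 + 50 * .logistic((wl - 570) / 45) -
      5 * .dip(wl, 540) - 8 * .dip(wl, 560) - 5 * .dip(wl, 580),
    hypervascularized = 12 + 40 * .logistic((wl - 600) / 35) -
      14 * .dip(wl, 540) - 11 * .dip(wl, 560) - 14 * .dip(wl, 580),
    ## background: mixture of >= 3 distinct operating-field materials
    ## (neutral drape, bluish metallic retractor, greenish marker)
    bgMaterials = cbind(
      rep(45, length(wl)),
      60 - 30 * .logistic((wl - 550) / 60),
      20 + 20 * exp(-0.5 * ((wl - 530) / 40)^2)))
}

#' Build the default class spectral signatures
#'
#' Constructs parametric mean/stdev signatures for the four classes over the
#' given grid. Tissue classes carry hemoglobin absorption valleys within
#' 540-580 nm (deepest for hypervascularized tissue); the background is a
#' mixture of three distinct material spectra and therefore has the largest
#' standard deviation. Construction is deterministic.
#'
#' @param grid \linkS4class{SpectralGrid} spanning at least 440-902 nm.
#' @param contrast Global class-separability dial in [0, 1]: class means are
#'   shrunk toward their common (grand) mean by this factor. 1 = full
#'   separation, 0 = all class means identical (chance-level scenes).
#' @param tumorContrast Tumor-vs-normal dial in [0, 1]: the tumor mean is
#'   interpolated between the normal mean (0) and its own curve (1).
#' @param patientOffsetSd Magnitude (reflectance units, 0-100 scale) of the
#'   smooth per-patient mean shifts applied at generation time.
#' @return List of four \linkS4class{ClassSignatureModel} objects, in class
#'   code order (normal, tumor, hypervascularized, background).
#' @examples
#' sigs <- buildDefaultSignatures(defaultGrid())
#' sigs[[3]]  # hypervascularized
#' @export
buildDefaultSignatures <- function(grid, contrast = 1, tumorContrast = 1,
                                   patientOffsetSd = 1.5) {
  wl <- wavelengths(grid)
  if (lambdaMin(grid) > 440 || lambdaMax(grid) < 902)
    stop("signatures undefined for grid (must span 440-902 nm)")
  stopifnot(contrast >= 0, contrast <= 1,
            tumorContrast >= 0, tumorContrast <= 1)
  bc <- .baseCurves(wl)
  tumor <- bc$normal + tumorContrast * (bc$tumor - bc$normal)
  bgMean <- rowMeans(bc$bgMaterials)
  means <- cbind(normal = bc$normal, tumor = tumor,
                 hypervascularized = bc$hypervascularized,
                 background = bgMean)
  grand <- rowMeans(means)
  means <- grand + contrast * (means - grand)
  means[means < 0] <- 0

  ## the contrast dial also interpolates the stdev spectra toward their
  ## common mean, so that at contrast 0 the classes are exchangeable and
  ## classification is at chance
  t01 <- (wl - wl[1]) / (wl[length(wl)] - wl[1])
  sdev <- cbind(
    normal = 2.0 + 0.5 * t01,
    tumor = 2.5 + 0.5 * t01,
    hypervascularized = 2.2 + 0.5 * t01,
    background = 4 + sqrt(rowMeans((bc$bgMaterials - bgMean)^2)))
  grandSd <- rowMeans(sdev)
  sdev <- grandSd + contrast * (sdev - grandSd)

  lapply(seq_along(.CLASS_NAMES), function(i)
    new("ClassSignatureModel", classId = .CLASS_NAMES[i],
        meanSpectrum = unname(means[, i]),
        stdevSpectrum = unname(sdev[, i]),
        patientOffsetSd = patientOffsetSd))
}

## Smooth low-frequency per-patient offset curve: a random constant plus a
## half-period sinusoid, scaled to the configured magnitude.
.patientOffset <- function(nBands, sd) {
  t01 <- seq(0, 1, length.out = nBands)
  z <- rnorm(2)
  sd * (z[1] + z[2] * sin(pi * t01)) / sqrt(2)
}

.checkSignatures <- function(spec, signatures) {
  nb <- nBands(spec@grid)
  ok <- vapply(signatures, function(s)
    length(s@meanSpectrum) == nb, logical(1))
  if (!all(ok))
    stop("signature length does not match the grid band count")
  ids <- vapply(signatures, function(s) s@classId, character(1))
  if (!identical(sort(ids), sort(.CLASS_NAMES)))
    stop("signatures must cover the four classes exactly once")
  signatures[match(.CLASS_NAMES, ids)]
}

#' Generate a labeled synthetic pixel dataset
#'
#' Draws \code{pixelsPerClassPerPatient} pixels per class per patient. Each
#' pixel is the class mean plus a smooth per-patient offset plus per-band
#' Gaussian noise scaled by the class stdev spectrum, clipped at zero.
#' Bitwise reproducible from the spec seed.
#'
#' @param spec A \linkS4class{SyntheticSceneSpec}.
#' @param signatures List of four \linkS4class{ClassSignatureModel}s (default
#'   \code{buildDefaultSignatures(spec@grid)}).
#' @param zeroContrastPatient Optional patient index (1-based): that
#'   patient's tumor pixels are drawn from the normal signature, emulating
#'   an acquisition in which the tumor is spectrally indistinct.
#' @return A \linkS4class{LabeledDataset} on the 0-100 reflectance scale
#'   (calibrated, not normalized).
#' @examples
#' sp <- syntheticSceneSpec(nPatients = 2, pixelsPerClassPerPatient = 50)
#' ds <- generateDataset(sp)
#' nPixels(ds)
#' @export
generateDataset <- function(spec, signatures = buildDefaultSignatures(spec@grid),
                            zeroContrastPatient = NA_integer_) {
  signatures <- .checkSignatures(spec, signatures)
  nb <- nBands(spec@grid)
  np <- spec@nPatients
  ppc <- spec@pixelsPerClassPerPatient
  total <- np * 4L * ppc
  withr::with_seed(spec@seed, {
    X <- matrix(0, nrow = nb, ncol = total)
    labels <- integer(total)
    pids <- character(total)
    col <- 0L
    for (p in seq_len(np)) {
      pid <- sprintf("P%03d", p)
      offsets <- lapply(signatures, function(s)
        .patientOffset(nb, s@patientOffsetSd))
      for (ci in 1:4) {
        oi <- ci
        if (ci == 2L && !is.na(zeroContrastPatient) &&
            p == zeroContrastPatient)
          oi <- 1L  # tumor drawn from the normal signature and offset
        sig <- signatures[[oi]]
        mu <- sig@meanSpectrum + offsets[[oi]]
        noise <- matrix(rnorm(nb * ppc, sd = sig@stdevSpectrum),
                        nrow = nb, ncol = ppc)
        px <- pmax(mu + noise, 0)
        X[, col + seq_len(ppc)] <- px
        labels[col + seq_len(ppc)] <- ci - 1L
        pids[col + seq_len(ppc)] <- pid
        col <- col + ppc
      }
    }
    labeledDataset(X, labels, pids, paste0(pids, "-01"), spec@grid)
  })
}

#' Generate a synthetic hyperspectral cube with a ground-truth map
#'
#' Lays out spatially contiguous class regions on a height x width scene:
#' a background border, a rectangular tumor blob covering a configurable
#' share of the labeled pixels (surrounded by a one-pixel unlabeled ring),
#' two vertical hypervascularized vessel strips, and normal parenchyma
#' elsewhere. A \code{glareFraction} of pixels is replaced by near-saturated
#' flat spectra and marked unlabeled.
#'
#' @param spec A \linkS4class{SyntheticSceneSpec} (its glareFraction and
#'   seed are used).
#' @param signatures Signature list as in \code{\link{generateDataset}}.
#' @param height,width Spatial dimensions in pixels.
#' @param tumorShare Tumor fraction of the labeled pixels (default 0.1).
#' @param patient Patient index (1-based) whose offset curve is applied.
#' @return List with elements \code{cube} (\linkS4class{HSCube}, calibrated
#'   0-100 scale) and \code{map} (integer matrix of codes 0/1/2/3/255).
#' @export
generateCube <- function(spec, signatures = buildDefaultSignatures(spec@grid),
                         height = 64L, width = 64L, tumorShare = 0.1,
                         patient = 1L) {
  signatures <- .checkSignatures(spec, signatures)
  if (height < 16L || width < 16L)
    stop("region packing impossible: scene must be at least 16 x 16")
  nb <- nBands(spec@grid)
  map <- matrix(3L, nrow = height, ncol = width)  # background border
  bw <- max(2L, round(0.08 * min(height, width)))
  map[(bw + 1):(height - bw), (bw + 1):(width - bw)] <- 0L  # normal

  ## vessel strips: two vertical hypervascularized bands in the inner region
  innerCols <- (bw + 1):(width - bw)
  v1 <- innerCols[max(1L, round(length(innerCols) * 0.65))]
  v2 <- innerCols[max(1L, round(length(innerCols) * 0.85))]
  map[(bw + 1):(height - bw), c(v1, v1 + 1L)] <- 2L
  map[(bw + 1):(height - bw), c(v2, v2 + 1L)] <- 2L

  ## tumor blob: contiguous block filled row by row to the exact share of
  ## labeled pixels, with a 1-pixel unlabeled separation ring
  nLabeled <- sum(map != .UNLABELED)
  nTumor <- max(1L, round(tumorShare * nLabeled))
  tw <- max(2L, floor(sqrt(nTumor)))
  r0 <- bw + 2L; c0 <- bw + 2L
  if (c0 + tw > v1 - 2L) tw <- max(2L, v1 - 2L - c0)
  rows <- ceiling(nTumor / tw)
  if (r0 + rows > height - bw - 1L)
    stop("region packing impossible: tumor blob does not fit")
  left <- nTumor
  for (r in seq_len(rows)) {
    k <- min(tw, left)
    map[r0 + r - 1L, c0:(c0 + k - 1L)] <- 1L
    left <- left - k
  }
  ## unlabeled ring around the blob
  rr <- (r0 - 1L):(r0 + rows)
  cc <- (c0 - 1L):(c0 + tw)
  ringMask <- matrix(FALSE, height, width)
  ringMask[rr, cc] <- TRUE
  ringMask[map == 1L] <- FALSE
  map[ringMask] <- .UNLABELED

  withr::with_seed(deriveSeed(spec@seed, paste0("cube", patient)), {
    offsets <- lapply(signatures, function(s)
      .patientOffset(nb, s@patientOffsetSd))
    vals <- array(0, dim = c(height, width, nb))
    for (ci in 1:4) {
      sel <- which(map == ci - 1L)
      if (!length(sel)) next
      sig <- signatures[[ci]]
      mu <- sig@meanSpectrum + offsets[[ci]]
      px <- pmax(mu + matrix(rnorm(nb * length(sel),
                                   sd = sig@stdevSpectrum),
                             nrow = nb), 0)
      for (b in seq_len(nb)) {
        plane <- vals[, , b]
        plane[sel] <- px[b, ]
        vals[, , b] <- plane
      }
    }
    ## unlabeled ring pixels get normal-like tissue so they are not empty
    sel <- which(map == .UNLABELED)
    if (length(sel)) {
      mu <- signatures[[1]]@meanSpectrum + offsets[[1]]
      px <- pmax(mu + matrix(rnorm(nb * length(sel),
                                   sd = signatures[[1]]@stdevSpectrum),
                             nrow = nb), 0)
      for (b in seq_len(nb)) {
        plane <- vals[, , b]
        plane[sel] <- px[b, ]
        vals[, , b] <- plane
      }
    }
    ## specular glare: near-saturated flat spectra, marked unlabeled
    if (spec@glareFraction > 0) {
      nGlare <- round(spec@glareFraction * height * width)
      gsel <- sample(height * width, nGlare)
      glareLevel <- runif(nGlare, 97, 100)
      for (b in seq_len(nb)) {
        plane <- vals[, , b]
        plane[gsel] <- glareLevel
        vals[, , b] <- plane
      }
      map[gsel] <- .UNLABELED
    }
    list(cube = hsCube(vals, spec@grid,
                       patientId = sprintf("P%03d", patient),
                       imageId = sprintf("P%03d-01", patient),
                       calibrated = TRUE),
         map = map)
  })
}

#' Flatten the labeled pixels of a cube into a LabeledDataset
#'
#' @param cube An \linkS4class{HSCube}.
#' @param map Ground-truth matrix of class codes (255 = unlabeled, dropped).
#' @return A \linkS4class{LabeledDataset} of the labeled pixels.
#' @export
cubeToDataset <- function(cube, map) {
  d <- dim(cube@values)
  if (!all(dim(map) == d[1:2])) stop("map dimensions do not match cube")
  sel <- which(map != .UNLABELED)
  if (!length(sel)) stop("no labeled pixels in map")
  flat <- matrix(cube@values, nrow = d[1] * d[2], ncol = d[3])
  labeledDataset(t(flat[sel, , drop = FALSE]), as.integer(map[sel]),
                 rep(cube@patientId, length(sel)),
                 rep(cube@imageId, length(sel)), cube@grid)
}
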