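mkCube <- function(vals, wl, calibrated = FALSE) {
  hsCube(vals, spectralGrid(wl), calibrated = calibrated)
}

test_that("calibration follows the white/dark reference rule", {
  g <- c(500, 600)
  dims <- c(2, 2, 2)
  D <- array(10, dims); W <- array(110, dims)
  refs <- referencePair(W, D)
  ## R = D -> 0; R = W -> 100; R = 55 -> 45
  expect_true(all(calibrate(mkCube(D, g), refs)@values == 0))
  expect_true(all(calibrate(mkCube(W, g), refs)@values == 100))
  out <- calibrate(mkCube(array(55, dims), g), refs)
  expect_true(all(out@values == 45))
  expect_true(out@calibrated)
  ## degenerate reference rejected
  expect_error(referencePair(D, D), "exceed")
  badRefs <- list(white = D, dark = D)
  expect_error(calibrate(mkCube(array(55, dims), g), badRefs),
               "degenerate")
})

test_that("extreme-band removal keeps the requested window", {
  wl <- seq(400, 1000, by = 100)
  cube <- mkCube(array(seq_len(4 * 7), c(2, 2, 7)), wl)
  kept <- removeExtremeBands(cube, 440, 902)
  expect_equal(wavelengths(kept), seq(500, 900, by = 100))
  ## full span is the identity
  full <- removeExtremeBands(cube, 400, 1000)
  expect_identical(full@values, cube@values)
  expect_error(removeExtremeBands(cube, 1500, 2000), "no bands")
})

test_that("moving-average smoothing uses shrinking edge windows", {
  wl <- c(500, 510, 520)
  spec <- c(0, 3, 0)
  cube <- mkCube(array(rep(spec, each = 1), c(1, 1, 3)), wl)
  sm <- smoothSpectra(cube, 3)
  expect_equal(as.vector(sm@values), c(1.5, 1, 1.5))
  ## window 1 is the identity; constant spectra are unchanged
  expect_identical(smoothSpectra(cube, 1)@values, cube@values)
  con <- mkCube(array(7, c(2, 2, 3)), wl)
  expect_equal(smoothSpectra(con, 3)@values, con@values)
  expect_error(smoothSpectra(cube, 2), "odd")
  expect_error(smoothSpectra(cube, 5), "exceeds")
})

test_that("per-pixel normalization maps each spectrum onto [0, 1]", {
  wl <- c(500, 510, 520)
  cube <- mkCube(array(c(2, 4, 6), c(1, 1, 3)), wl, calibrated = TRUE)
  nm <- normalizePixels(cube)
  expect_equal(as.vector(nm@values), c(0, 0.5, 1))
  expect_true(nm@normalized)
  ## idempotent on already-normalized pixels
  expect_equal(normalizePixels(nm)@values, nm@values)
  ## constant pixel becomes zeros with a warning
  con <- mkCube(array(5, c(1, 1, 3)), wl, calibrated = TRUE)
  expect_warning(z <- normalizePixels(con), "constant")
  expect_true(all(z@values == 0))
  ## calibration required first
  expect_error(normalizePixels(mkCube(array(1:3, c(1, 1, 3)), wl)),
               "calibrated")
})

test_that("normalization is invariant to per-pixel affine gain", {
  set.seed(4)
  M <- matrix(runif(20 * 30), 20, 30)
  g <- spectralGrid(seq(440, 902, length.out = 20))
  ds <- labeledDataset(M, rep(0:3, length.out = 30),
                       rep("P1", 30), grid = g)
  ds2 <- labeledDataset(3.7 * M + 11, rep(0:3, length.out = 30),
                        rep("P1", 30), grid = g)
  expect_equal(spectra(normalizePixels(ds)), spectra(normalizePixels(ds2)))
})

test_that("sampling interval arithmetic", {
  expect_equal(round(samplingInterval(440, 902, 128), 2), 3.61)
  expect_equal(round(samplingInterval(400, 1000, 826), 2), 0.73)
  expect_equal(samplingInterval(440, 902, 8), 57.75)
  expect_error(samplingInterval(440, 902, 0), "nBands")
})

test_that("decimation picks nearest bands to interval midpoints", {
  wl <- seq(440, 530, by = 10)  # 10-band toy grid
  cube <- mkCube(array(seq_len(10), c(1, 1, 10)), wl)
  dec <- decimateBands(cube, 6)
  interval <- (530 - 440) / 6
  targets <- 440 + (seq_len(6) - 0.5) * interval
  expect_length(wavelengths(dec), 6)
  expect_true(all(abs(wavelengths(dec) - targets) <= interval / 2 + 1e-9))
  ## full count is the identity; single band lands at the grid midpoint
  expect_identical(decimateBands(cube, 10)@values, cube@values)
  one <- decimateBands(cube, 1)
  expect_equal(wavelengths(one), wl[which.min(abs(wl - 485))])
  expect_error(decimateBands(cube, 11), "between")
  ## no band is ever selected twice
  wlDense <- c(440, 441, 442, 600, 800, 900)
  cd <- decimateBands(mkCube(array(1:6, c(1, 1, 6)), wlDense), 5)
  expect_equal(length(unique(wavelengths(cd))), 5)
})

test_that("band removal and decimation commute inside the kept range", {
  wl <- seq(400, 1000, by = 5)
  vals <- array(rnorm(4 * length(wl)), c(2, 2, length(wl)))
  cube <- mkCube(vals, wl)
  a <- decimateBands(removeExtremeBands(cube, 440, 902), 16)
  b <- removeExtremeBands(
    decimateBands(removeExtremeBands(cube, 440, 902), 16), 440, 902)
  expect_equal(wavelengths(a), wavelengths(b))
  expect_identical(a@values, b@values)
})

test_that("LabeledDataset preprocessing matches the cube path", {
  sp <- syntheticSceneSpec(nPatients = 2, pixelsPerClassPerPatient = 20,
                           seed = 31)
  ds <- generateDataset(sp)
  sm <- smoothSpectra(ds, 5)
  expect_equal(dim(spectra(sm)), dim(spectra(ds)))
  dec <- decimateBands(ds, 32)
  expect_equal(nBands(dec), 32)
  expect_equal(pixelLabels(dec), pixelLabels(ds))
  nm <- suppressWarnings(normalizePixels(ds))
  rng <- apply(spectra(nm), 2, range)
  expect_true(all(rng[1, ] == 0) && all(rng[2, ] <= 1))
})
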