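test_that("default signatures reproduce hemoglobin absorption structure", {
  g <- defaultGrid()
  sigs <- buildDefaultSignatures(g)
  expect_length(sigs, 4)
  for (s in sigs) {
    expect_length(s@meanSpectrum, nBands(g))
    expect_true(all(s@stdevSpectrum >= 0))
  }
  wl <- wavelengths(g)
  nearest <- function(nm) which.min(abs(wl - nm))
  hyper <- sigs[[3]]@meanSpectrum
  normal <- sigs[[1]]@meanSpectrum
  ## hemoglobin valley: reflectance at 560 nm below 650 nm
  expect_lt(hyper[nearest(560)], hyper[nearest(650)])
  expect_lt(normal[nearest(560)], normal[nearest(650)])
  ## hypervascularized valleys deeper than normal (relative to 650 nm)
  expect_gt(normal[nearest(560)] / normal[nearest(650)],
            hyper[nearest(560)] / hyper[nearest(650)])
  ## background mixture has the largest dispersion
  tissueSd <- mean(vapply(sigs[1:3], function(s) mean(s@stdevSpectrum),
                          numeric(1)))
  expect_gt(mean(sigs[[4]]@stdevSpectrum), tissueSd)
  ## deterministic construction
  expect_identical(sigs, buildDefaultSignatures(g))
  ## grid outside the visible range is rejected
  expect_error(buildDefaultSignatures(spectralGrid(seq(900, 1700, 10))),
               "signatures undefined")
})

test_that("generateDataset yields the requested pixels, reproducibly", {
  sp <- syntheticSceneSpec(nPatients = 4, pixelsPerClassPerPatient = 50,
                           seed = 3)
  ds <- generateDataset(sp)
  expect_equal(nPixels(ds), 4 * 4 * 50)
  expect_equal(unname(table(pixelLabels(ds))), rep(200L, 4),
               ignore_attr = TRUE)
  expect_length(unique(patientIds(ds)), 4)
  expect_true(all(spectra(ds) >= 0))
  expect_identical(spectra(generateDataset(sp)), spectra(ds))
})

test_that("per-class sample means converge to the signature means", {
  ## offsets disabled so the sample mean estimates the signature directly
  g <- spectralGrid(seq(440, 902, length.out = 32))
  sigs <- buildDefaultSignatures(g, patientOffsetSd = 0)
  sp <- syntheticSceneSpec(grid = g, nPatients = 2,
                           pixelsPerClassPerPatient = 5000, seed = 9)
  ds <- generateDataset(sp, sigs)
  M <- spectra(ds)
  labs <- pixelLabels(ds)
  for (cl in 0:3) {
    X <- M[, labs == cl]
    n <- ncol(X)
    mu <- rowMeans(X)
    se <- apply(X, 1, sd) / sqrt(n)
    target <- sigs[[cl + 1]]@meanSpectrum
    ## clipping at zero can only bias upward where the mean is tiny;
    ## all default means are far from zero so 3 SE should hold everywhere
    expect_true(all(abs(mu - target) < 3 * se + 1e-9),
                label = sprintf("class %d mean within 3 SE", cl))
  }
})

test_that("patient offsets shift patient means but not the class shape", {
  sp <- syntheticSceneSpec(nPatients = 4, pixelsPerClassPerPatient = 200,
                           seed = 5)
  ds <- generateDataset(sp)
  M <- spectra(ds)
  sel <- pixelLabels(ds) == 0
  perPatient <- vapply(unique(patientIds(ds)), function(p)
    mean(M[, sel & patientIds(ds) == p]), numeric(1))
  expect_gt(diff(range(perPatient)), 0.1)
})

test_that("a zero-contrast patient has tumor indistinct from normal", {
  sp <- syntheticSceneSpec(nPatients = 3, pixelsPerClassPerPatient = 300,
                           seed = 13)
  ds <- generateDataset(sp, zeroContrastPatient = 2L)
  M <- spectra(ds)
  isP2 <- patientIds(ds) == "P002"
  tum <- rowMeans(M[, isP2 & pixelLabels(ds) == 1])
  nor <- rowMeans(M[, isP2 & pixelLabels(ds) == 0])
  ## identical generating distribution: differences are pure sampling noise
  expect_lt(mean(abs(tum - nor)), 0.3)
  tum1 <- rowMeans(M[, !isP2 & pixelLabels(ds) == 1])
  nor1 <- rowMeans(M[, !isP2 & pixelLabels(ds) == 0])
  expect_gt(max(abs(tum1 - nor1)), 2)
})

test_that("generateCube lays out labeled regions, glare and codes", {
  sp <- syntheticSceneSpec(nPatients = 2, pixelsPerClassPerPatient = 10,
                           glareFraction = 0.05, seed = 21)
  out <- generateCube(sp, height = 48, width = 48, tumorShare = 0.1)
  expect_true(all(out$map %in% c(0:3, 255L)))
  expect_true(all(dim(out$cube@values)[1:2] == c(48, 48)))
  ## all four classes present and contiguous tumor blob near the share
  expect_setequal(intersect(unique(as.vector(out$map)), 0:3), 0:3)
  ## glare pixels are flat near-saturated spectra marked unlabeled
  d <- dim(out$cube@values)
  M <- t(matrix(out$cube@values, d[1] * d[2], d[3]))
  flat <- apply(M, 2, function(p) max(p) - min(p)) < 1e-9
  expect_true(all(out$map[flat] == 255L))
  expect_true(all(M[, flat] > 95))
  ## glare_fraction = 0 leaves no saturated flat pixels
  sp0 <- syntheticSceneSpec(nPatients = 2, pixelsPerClassPerPatient = 10,
                            glareFraction = 0, seed = 21)
  out0 <- generateCube(sp0, height = 48, width = 48)
  M0 <- t(matrix(out0$cube@values, 48 * 48, nBands(out0$cube)))
  expect_false(any(apply(M0, 2, function(p) max(p) - min(p)) < 1e-9))
  ## tumor share of labeled pixels is honored closely
  nLab <- sum(out0$map != 255L)
  expect_lt(abs(sum(out0$map == 1L) / nLab - 0.1), 0.02)
  ## impossible packing errors out
  expect_error(generateCube(sp0, height = 10, width = 10), "packing")
})

test_that("cubeToDataset extracts exactly the labeled pixels", {
  sp <- syntheticSceneSpec(nPatients = 2, pixelsPerClassPerPatient = 10,
                           glareFraction = 0.03, seed = 2)
  out <- generateCube(sp, height = 32, width = 32)
  ds <- cubeToDataset(out$cube, out$map)
  expect_equal(nPixels(ds), sum(out$map != 255L))
  expect_true(all(pixelLabels(ds) %in% 0:3))
  expect_error(cubeToDataset(out$cube, out$map[1:10, 1:10]), "dimensions")
})

test_that("scene separability is governed by the contrast dial", {
  ## max contrast: a linear classifier generalizes across patients;
  ## zero contrast: classes are exchangeable and accuracy sits at chance
  ds <- smallScene()
  res <- evaluateLOPO(ds)
  expect_gte(res$summary$mean[res$summary$metric == "oa"], 0.95)
  sp <- syntheticSceneSpec(nPatients = 3, pixelsPerClassPerPatient = 120,
                           seed = 7)
  sig0 <- buildDefaultSignatures(defaultGrid(), contrast = 0)
  ds0 <- suppressWarnings(normalizePixels(generateDataset(sp, sig0)))
  oa0 <- evaluateLOPO(ds0)$summary
  expect_lt(abs(oa0$mean[oa0$metric == "oa"] - 0.25), 0.05)
})
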