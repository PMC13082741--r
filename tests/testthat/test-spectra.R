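# ROI mean spectra, normalization, per-band tests, extrema.

mkSpectrum <- function(values, wl = seq_along(values) + 500,
                       param = "DOP", id = "c1", cls = "granulocyte") {
  new("Spectrum", wavelengths = as.numeric(wl), values = as.numeric(values),
      nPixels = 10L, parameter = param, cellId = id, classLabel = cls)
}

test_that("mean spectra average only the ROI foreground", {
  pl <- array(0.7, c(10, 10, 4))
  m <- matrix(FALSE, 10, 10); m[2:4, 2:4] <- TRUE
  s <- extractMeanSpectrum(pl, m, c(500, 550, 600, 650))
  expect_equal(spectrumValues(s), rep(0.7, 4))
  expect_equal(s@nPixels, 9L)

  # single-pixel mask returns that pixel's band values
  pl2 <- array(rnorm(10 * 10 * 4), c(10, 10, 4))
  m1 <- matrix(FALSE, 10, 10); m1[5, 7] <- TRUE
  expect_equal(spectrumValues(extractMeanSpectrum(pl2, m1, 1:4 + 500)),
               pl2[5, 7, ])

  # background content outside the mask is irrelevant
  pl3 <- pl2; pl3[!array(m, dim(pl3))] <- 99
  m2 <- matrix(FALSE, 10, 10); m2[2:4, 2:4] <- TRUE
  expect_equal(spectrumValues(extractMeanSpectrum(pl3, m2, 1:4 + 500)),
               spectrumValues(extractMeanSpectrum(pl2, m2, 1:4 + 500)))

  expect_error(extractMeanSpectrum(pl, matrix(FALSE, 10, 10), 1:4), "empty")
  expect_error(extractMeanSpectrum(pl, matrix(TRUE, 9, 10), 1:4),
               "spatial grid")
})

test_that("class-distinct depolarization separates masked DOP spectra", {
  sp <- phantomSpec(imageSize = 100,
                    nCellsPerClass = c(granulocyte = 1, lymphocyte = 1,
                                       monocyte = 0),
                    cellRadiusRange = c(8, 10), classDepolSD = 0,
                    seed = 81)
  sc <- generatePhantom(sp)
  stk <- simulateAcquisition(sc, noiseModel = list(type = "none"))
  dv <- computeDerived(computeStokes(stk))
  cr <- cellRecords(sc)
  gId <- cr$cellId[cr$class == "granulocyte"]
  lId <- cr$cellId[cr$class == "lymphocyte"]
  dopPlane <- cubePlane(dv, "DOP")
  g <- spectrumValues(extractMeanSpectrum(dopPlane, cellMask(sc, gId),
                                          wavelengths(sc)))
  l <- spectrumValues(extractMeanSpectrum(dopPlane, cellMask(sc, lId),
                                          wavelengths(sc)))
  expect_true(all(g - l > 0))   # 0.5 vs 0.3: constant-sign gap at all bands
})

test_that("spectrum normalization follows the chosen method", {
  s <- mkSpectrum(c(2, 4, 8))
  expect_equal(spectrumValues(normalizeSpectrum(s, "max")),
               c(0.25, 0.5, 1))
  expect_equal(spectrumValues(normalizeSpectrum(mkSpectrum(c(1, 1, 2)),
                                                "area")),
               c(0.25, 0.25, 0.5))
  expect_equal(normalizeSpectrum(s, "none"), s)
  expect_error(normalizeSpectrum(mkSpectrum(c(0, 0, 0)), "max"),
               "all-zero")
})

test_that("identical groups give p = 1 at every band and swapping is symmetric", {
  a <- lapply(1:5, function(i) mkSpectrum(c(i, i + 1, i + 2)))
  same <- perBandTTest(a, a)
  expect_equal(same@pValues, rep(1, 3))

  set.seed(91)
  b <- lapply(1:6, function(i) mkSpectrum(rnorm(3, mean = 2)))
  ab <- perBandTTest(a, b)
  ba <- perBandTTest(b, a)
  expect_equal(ab@pValues, ba@pValues, tolerance = 1e-12)
  expect_equal(unname(ab@groupSizes), c(5L, 6L))
  expect_equal(rev(unname(ba@groupSizes)), c(5L, 6L))

  # BH adjustment reported alongside, never replacing raw values
  expect_equal(ab@pAdjusted, stats::p.adjust(ab@pValues, "BH"))
  expect_true(all(ab@pAdjusted >= ab@pValues))

  expect_error(perBandTTest(a[1], b), "at least 2")
  expect_error(perBandTTest(a, lapply(1:4, function(i)
    mkSpectrum(1:4, wl = 1:4 + 500))), "band")
})

test_that("Welch test holds its type-I error under the null", {
  set.seed(92)
  reps <- 2000
  p <- replicate(reps, {
    x <- rnorm(15); y <- rnorm(15, sd = 1.5)
    stats::t.test(x, y)$p.value
  })
  rate <- mean(p < 0.05)
  expect_gt(rate, 0.03); expect_lt(rate, 0.07)
  # the per-band wrapper agrees with t.test band by band
  A <- matrix(rnorm(15 * 4), 15); B <- matrix(rnorm(15 * 4), 15)
  ours <- perBandTTest(A, B, wavelengths = c(500, 550, 600, 650))@pValues
  ref <- vapply(1:4, function(b) stats::t.test(A[, b], B[, b])$p.value,
                numeric(1))
  expect_equal(ours, ref, tolerance = 1e-12)
})

test_that("well-separated phantom classes give small p at n = 15 per group", {
  # per-cell mean DOP values: effect of two pooled SDs at n = 15 + 15
  set.seed(93)
  wl <- seq(470, 750, 10)
  A <- matrix(rnorm(15 * 29, mean = 0.5, sd = 0.05), 15)
  B <- matrix(rnorm(15 * 29, mean = 0.4, sd = 0.05), 15)
  ps <- perBandTTest(A, B, wavelengths = wl)@pValues
  expect_gt(mean(ps < 0.05), 0.5)
})

test_that("extrema detection finds interior peaks and troughs in order", {
  expect_equal(findSpectralExtrema(c(1, 3, 1), wavelengths = c(470, 480,
                                                               490)),
               data.frame(wavelength = 480, value = 3, kind = "peak"))
  expect_equal(nrow(findSpectralExtrema(1:10, wavelengths = 1:10 + 500)),
               0)
  # plateau peak reports its shortest wavelength
  ext <- findSpectralExtrema(c(1, 3, 3, 1), wavelengths = c(470, 480, 490,
                                                            500))
  expect_equal(ext$wavelength, 480)

  # three-lobe curve: maxima injected near 475 and 550 nm, a stain-like
  # dip carved out at 525 nm
  wl <- seq(470, 750, by = 5)
  curve <- exp(-0.5 * ((wl - 475) / 12)^2) +
    0.8 * exp(-0.5 * ((wl - 550) / 18)^2) -
    0.3 * exp(-0.5 * ((wl - 525) / 8)^2)
  ext <- findSpectralExtrema(curve, wavelengths = wl)
  peaks <- ext$wavelength[ext$kind == "peak"]
  troughs <- ext$wavelength[ext$kind == "trough"]
  expect_equal(length(peaks), 2)
  expect_lte(abs(peaks[1] - 475), 5)
  expect_lte(abs(peaks[2] - 550), 5)
  expect_equal(length(troughs), 1)
  expect_lte(abs(troughs - 525), 15)
})

test_that("DOP spectra discriminate classes better than S0 when S0 contrast is small", {
  # both classes share the stain (equal chromatin density), differ only in
  # depolarization: DOP p-values should be stochastically smaller than S0's
  # raise the staining variability so the classes' S0 separation is small
  # relative to between-cell scatter, as the property prescribes
  sp <- phantomSpec(imageSize = 150,
                    nCellsPerClass = c(granulocyte = 6, lymphocyte = 6,
                                       monocyte = 0),
                    cellRadiusRange = c(6, 8), stainUptakeSD = 0.25,
                    seed = 95)
  sc <- generatePhantom(sp)
  stk <- simulateAcquisition(sc, noiseModel = list(type = "gaussian",
                                                   sd = 0.01), seed = 96)
  st <- computeStokes(stk)
  dv <- computeDerived(st)
  spectra <- extractCellSpectra(sc, st, dv, parameters = c("S0", "DOP"))
  grab <- function(param, cls) {
    sub <- spectra[spectra$parameter == param & spectra$class == cls, ]
    t(vapply(unique(sub$cellId),
             function(id) sub$value[sub$cellId == id],
             numeric(length(wavelengths(sc)))))
  }
  pS0 <- perBandTTest(grab("S0", "granulocyte"), grab("S0", "lymphocyte"),
                      wavelengths = wavelengths(sc))@pValues
  pDOP <- perBandTTest(grab("DOP", "granulocyte"),
                       grab("DOP", "lymphocyte"),
                       wavelengths = wavelengths(sc))@pValues
  expect_lt(median(pDOP), median(pS0))
  expect_gte(mean(pDOP < 0.05), mean(pS0 < 0.05))
})
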