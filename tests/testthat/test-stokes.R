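# Stokes reconstruction and derived degree-of-polarization maps.

mkStack <- function(ih, iv, i45, irc, wl = 550) {
  analyzerStack(matrix(ih), matrix(iv), matrix(i45), matrix(irc), wl)
}

stokesOf <- function(cube) {
  vapply(c("S0", "S1", "S2", "S3"),
         function(p) cubePlane(cube, p)[1, 1, 1], numeric(1))
}

test_that("computeStokes implements the four-analyzer reduction", {
  expect_equal(unname(stokesOf(computeStokes(mkStack(1, 0, 0.5, 0.5)))),
               c(1, 1, 0, 0))
  expect_equal(unname(stokesOf(computeStokes(mkStack(0.5, 0.5, 0.5, 0.5)))),
               c(1, 0, 0, 0))
  expect_equal(unname(stokesOf(computeStokes(mkStack(0.5, 0.5, 0.5, 1)))),
               c(1, 0, 0, 1))
  # matches the simulated identity-sample acquisition, closing the loop
  expect_equal(unname(stokesOf(computeStokes(mkStack(0.25, 0.25, 0.5,
                                                     0.25)))),
               c(0.5, 0, 0.5, 0))
})

test_that("shape mismatches are rejected with the offending plane named", {
  expect_error(
    analyzerStack(array(1, c(4, 4, 2)), array(1, c(4, 4, 2)),
                  array(1, c(4, 5, 2)), array(1, c(4, 4, 2)),
                  wavelengths = c(500, 600)),
    "i45")
  expect_error(
    analyzerStack(array(1, c(4, 4, 2)), array(1, c(4, 4, 2)),
                  array(1, c(4, 4, 2)), array(1, c(4, 4, 2)),
                  wavelengths = c(500, 600, 700)),
    "wavelength")
})

test_that("round trip: reconstruction inverts the noiseless forward model", {
  s <- randomPhysicalStokes(1000, seed = 314)
  cfgs <- canonicalPSAConfigs()
  W <- t(vapply(cfgs, function(cfg) psaMueller(cfg)[1, ], numeric(4)))
  I <- s %*% t(W)    # n x 4 intensities: Ih, Iv, I45, Irc
  recon <- cbind(I[, 1] + I[, 2], I[, 1] - I[, 2],
                 2 * I[, 3] - (I[, 1] + I[, 2]),
                 2 * I[, 4] - (I[, 1] + I[, 2]))
  relErr <- abs(recon - s) / pmax(abs(s), 1e-300)
  # relative where the component is sizable, absolute near zero
  err <- abs(recon - s) / pmax(abs(s), s[, 1])
  expect_lt(max(err), 1e-10)

  # and through the full cube path for a subset
  n <- 100
  stk <- analyzerStack(array(I[1:n, 1], c(n, 1, 1)),
                       array(I[1:n, 2], c(n, 1, 1)),
                       array(I[1:n, 3], c(n, 1, 1)),
                       array(I[1:n, 4], c(n, 1, 1)), 550)
  cube <- computeStokes(stk)
  for (k in 1:4)
    expect_equal(drop(cubePlane(cube, paste0("S", k - 1))), s[1:n, k],
                 tolerance = 1e-10)
})

test_that("computeStokes is linear and DOP is scale-invariant", {
  sc <- generatePhantom(smallPhantom(nPerClass = 1, size = 64, seed = 6))
  stk <- simulateAcquisition(sc, noiseModel = list(type = "none"))
  c1 <- computeStokes(stk)
  scaled <- analyzerStack(3 * stk@ih, 3 * stk@iv, 3 * stk@i45, 3 * stk@irc,
                          wavelengths(stk))
  c3 <- computeStokes(scaled)
  expect_equal(c3@s0, 3 * c1@s0, tolerance = 1e-12)
  expect_equal(c3@s3, 3 * c1@s3, tolerance = 1e-12)
  d1 <- computeDerived(c1, s0Floor = 1e-6)
  d3 <- computeDerived(c3, s0Floor = 3e-6)
  expect_equal(d3@dop, d1@dop, tolerance = 1e-12)
  expect_equal(d3@dolp, d1@dolp, tolerance = 1e-12)
})

test_that("derived parameters evaluate the standard definitions", {
  dvOf <- function(s) {
    stk <- mkStack((s[1] + s[2]) / 2, (s[1] - s[2]) / 2,
                   (s[1] + s[3]) / 2, (s[1] + s[4]) / 2)
    dv <- computeDerived(computeStokes(stk), s0Floor = 0)
    vapply(c("DOP", "DOLP", "DOCP"),
           function(p) cubePlane(dv, p)[1, 1, 1], numeric(1))
  }
  expect_equal(unname(dvOf(c(1, 1, 0, 0))), c(1, 1, 0), tolerance = 1e-12)
  expect_equal(unname(dvOf(c(1, 0, 0, 1))), c(1, 0, 1), tolerance = 1e-12)
  # 3-4-5 identity: dolp 0.6, docp 0.8 compose to dop exactly 1
  expect_equal(unname(dvOf(c(1, 0.6, 0, 0.8))), c(1, 0.6, 0.8),
               tolerance = 1e-12)
  expect_equal(unname(dvOf(c(2, 1, 1, 0))),
               c(sqrt(2) / 2, sqrt(2) / 2, 0), tolerance = 1e-12)
})

test_that("dop = sqrt(dolp^2 + docp^2) identically at valid pixels", {
  sc <- generatePhantom(smallPhantom(nPerClass = 2, size = 90, seed = 8))
  stk <- simulateAcquisition(sc, noiseModel = list(type = "gaussian",
                                                   sd = 0.01), seed = 3)
  dv <- computeDerived(computeStokes(stk), clipPolicy = "allow")
  v <- validMask(dv)
  expect_true(any(v))
  expect_equal(dv@dop[v], sqrt(dv@dolp[v]^2 + dv@docp[v]^2),
               tolerance = 1e-12)
  # ordering invariants after clipping
  dvc <- computeDerived(computeStokes(stk), clipPolicy = "clip")
  expect_true(all(dvc@dolp[v] <= dvc@dop[v] + 1e-12))
  expect_true(all(dvc@docp[v] <= dvc@dop[v] + 1e-12))
  expect_true(all(dvc@dop >= 0 & dvc@dop <= 1))
  # invalid pixels are zeroed and flagged
  expect_true(all(dvc@dop[!v] == 0))
})

test_that("s0 floor masks dark pixels and the clip policy counts artifacts", {
  stk <- analyzerStack(array(c(0.5, 1e-9), c(2, 1, 1)),
                       array(c(0.5, 1e-9), c(2, 1, 1)),
                       array(c(0.5, 1e-9), c(2, 1, 1)),
                       array(c(0.5, 1e-9), c(2, 1, 1)), 550)
  dv <- computeDerived(computeStokes(stk))   # auto floor
  expect_true(validMask(dv)[1, 1, 1])
  expect_false(validMask(dv)[2, 1, 1])

  # constructed unphysical pixel: clip counts it, allow keeps the value
  stk2 <- mkStack(1.05, -0.05, 0.5, 0.5)   # s0 = 1, s1 = 1.1
  dvClip <- computeDerived(computeStokes(stk2), s0Floor = 0)
  expect_equal(clippedCount(dvClip), 2L)   # dop and dolp exceed 1; docp = 0
  expect_equal(cubePlane(dvClip, "DOP")[1, 1, 1], 1)
  dvAllow <- computeDerived(computeStokes(stk2), s0Floor = 0,
                            clipPolicy = "allow")
  expect_equal(cubePlane(dvAllow, "DOP")[1, 1, 1], 1.1, tolerance = 1e-12)
  expect_equal(clippedCount(dvAllow), 0L)
})

test_that("physicality report finds constructed and noise violations", {
  # noiseless cube: no violations at all
  sc <- generatePhantom(smallPhantom(nPerClass = 1, size = 48, seed = 12))
  stk0 <- simulateAcquisition(sc, noiseModel = list(type = "none"))
  rep0 <- physicalityReport(computeStokes(stk0))
  expect_equal(rep0$nTotal, 0)

  # one constructed unphysical pixel with excess 0.1
  stk1 <- mkStack(1.05, -0.05, 0.5, 0.5)
  rep1 <- physicalityReport(computeStokes(stk1))
  expect_equal(rep1$nTotal, 1)
  expect_equal(rep1$maxExcess, 0.1, tolerance = 1e-12)

  # 1% gaussian noise on a nearly fully polarized field: violations are
  # rare but nonzero (noise can only push DOP past 1 where it is already
  # close to 1; a bright weakly-polarized background sits far below S0)
  scHi <- generatePhantom(smallPhantom(nPerClass = 0, size = 48))
  scHi@depol[] <- 0.93
  stkN <- simulateAcquisition(scHi, noiseModel = list(type = "gaussian",
                                                      sd = 0.01), seed = 42)
  repN <- physicalityReport(computeStokes(stkN))
  expect_gt(repN$nTotal, 0)
  expect_lt(repN$fractionTotal, 0.05)
})

test_that("mean DOP over a cell rises strictly with the depolarization factor", {
  levels <- seq(0.15, 0.75, by = 0.15)
  meanDOP <- vapply(levels, function(d) {
    sp <- phantomSpec(imageSize = 56,
                      nCellsPerClass = c(granulocyte = 1, lymphocyte = 0,
                                         monocyte = 0),
                      cellRadiusRange = c(7, 9),
                      classDepolMean = c(granulocyte = d, lymphocyte = 0.3,
                                         monocyte = 0.4),
                      classDepolSD = 0, granuleDepolContrast = 0,
                      seed = 50)    # same seed: identical geometry
    sc <- generatePhantom(sp)
    stk <- simulateAcquisition(sc, noiseModel = list(type = "none"))
    dv <- computeDerived(computeStokes(stk), s0Floor = 0)
    mean(cubePlane(dv, "DOP")[cellMask(sc, 1)])
  }, numeric(1))
  expect_true(all(diff(meanDOP) > 0))
  expect_equal(cor(levels, meanDOP, method = "spearman"), 1)
})
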