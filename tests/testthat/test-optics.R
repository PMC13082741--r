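# Mueller-calculus elements and the polarization state generator/analyzer.

test_that("rotation Mueller matrices behave as frame rotations", {
  expect_equal(rotationMueller(0), diag(4))
  # rotations by a and -a cancel
  for (a in c(13, 45, 90, 161.5))
    expect_equal(rotationMueller(a) %*% rotationMueller(-a), diag(4),
                 tolerance = 1e-14)
  # 90 + 90 composes to a 180-degree frame rotation, whose doubled angle
  # is 360: it acts as the identity on (s1, s2)
  r180 <- rotationMueller(90) %*% rotationMueller(90)
  expect_equal(drop(r180 %*% c(1, 0.3, -0.7, 0.2)),
               c(1, 0.3, -0.7, 0.2), tolerance = 1e-14)
  expect_equal(r180, diag(4), tolerance = 1e-14)
  # the sign convention: 45-degree rotation sends horizontal to -s2
  expect_equal(drop(rotationMueller(45) %*% c(1, 1, 0, 0)),
               c(1, 0, -1, 0), tolerance = 1e-14)
})

test_that("ideal linear polarizer transmits and extinguishes correctly", {
  expect_equal(drop(linearPolarizer(0) %*% c(1, 0, 0, 0)),
               c(0.5, 0.5, 0, 0), tolerance = 1e-14)
  expect_equal(drop(linearPolarizer(0) %*% c(1, -1, 0, 0)),
               c(0, 0, 0, 0), tolerance = 1e-14)
  expect_equal(drop(linearPolarizer(45) %*% c(1, 0, 0, 0)),
               c(0.5, 0, 0.5, 0), tolerance = 1e-14)
  # any transmitted beam is fully polarized
  set.seed(42)
  for (axis in runif(5, 0, 180)) {
    out <- drop(linearPolarizer(axis) %*% drop(randomPhysicalStokes(1)))
    if (out[1] > 1e-12)
      expect_equal(sqrt(sum(out[2:4]^2)) / out[1], 1, tolerance = 1e-10)
  }
})

test_that("variable retarder matches its defining properties", {
  expect_equal(variableRetarder(0, 0), diag(4))
  expect_equal(variableRetarder(30, 2 * pi), diag(4), tolerance = 1e-14)
  # half-wave plate at 45 flips horizontal to vertical
  expect_equal(drop(variableRetarder(45, pi) %*% c(1, 1, 0, 0)),
               c(1, -1, 0, 0), tolerance = 1e-14)
  # quarter-wave at 0 turns +45 linear into right-circular (+S3)
  expect_equal(drop(variableRetarder(0, pi / 2) %*% c(1, 0, 1, 0)),
               c(1, 0, 0, 1), tolerance = 1e-14)
  # S0 is never altered
  set.seed(7)
  s <- randomPhysicalStokes(20)
  for (i in 1:20) {
    out <- drop(variableRetarder(runif(1, 0, 180), runif(1, 0, 2 * pi)) %*%
                  s[i, ])
    expect_equal(out[1], s[i, 1], tolerance = 1e-12)
  }
})

test_that("element constructors agree with the Jones-calculus oracle", {
  set.seed(123)
  for (rep in 1:25) {
    axis <- runif(1, -90, 270)
    delta <- runif(1, 0, 2 * pi)
    expect_equal(linearPolarizer(axis), jonesToMueller(jonesPolarizer(axis)),
                 tolerance = 1e-12)
    expect_equal(variableRetarder(axis, delta),
                 jonesToMueller(jonesRetarder(axis, delta)),
                 tolerance = 1e-12)
  }
})

test_that("passive elements never amplify total intensity", {
  set.seed(99)
  s <- randomPhysicalStokes(50)
  elements <- list(linearPolarizer(runif(1, 0, 180)),
                   variableRetarder(runif(1, 0, 180), runif(1, 0, 2 * pi)),
                   partialDepolarizer(runif(1)),
                   rotationMueller(runif(1, 0, 360)))
  for (el in elements) for (i in seq_len(nrow(s))) {
    out <- drop(el %*% s[i, ])
    expect_lte(out[1], s[i, 1] + 1e-12)
    expect_gte(out[1], -1e-12)
  }
})

test_that("canonical PSA configurations realize the four named analyzers", {
  cfgs <- canonicalPSAConfigs()
  expect_named(cfgs, c("Ih", "Iv", "I45", "Irc"))
  expect_equal(c(cfgs$Ih@retardance1, cfgs$Ih@retardance2), c(0, 0))
  expect_equal(c(cfgs$Iv@retardance1, cfgs$Iv@retardance2), c(0, pi))
  expect_equal(c(cfgs$I45@retardance1, cfgs$I45@retardance2),
               c(pi / 2, pi / 2))
  expect_equal(c(cfgs$Irc@retardance1, cfgs$Irc@retardance2), c(0, pi / 2))

  # spot anchors that fix the sign convention
  expect_equal(psaIntensity(c(1, 1, 0, 0), cfgs$Ih), 1, tolerance = 1e-12)
  expect_equal(psaIntensity(c(1, 1, 0, 0), cfgs$Iv), 0, tolerance = 1e-12)
  expect_equal(psaIntensity(c(1, 0, 1, 0), cfgs$I45), 1, tolerance = 1e-12)
  expect_equal(psaIntensity(c(1, 0, 0, 1), cfgs$Irc), 1, tolerance = 1e-12)

  # the full identities for random physical input, to float precision
  s <- randomPhysicalStokes(200, seed = 5)
  expected <- cbind(0.5 * (s[, 1] + s[, 2]), 0.5 * (s[, 1] - s[, 2]),
                    0.5 * (s[, 1] + s[, 3]), 0.5 * (s[, 1] + s[, 4]))
  for (i in seq_len(nrow(s)))
    for (k in seq_along(cfgs))
      expect_equal(psaIntensity(s[i, ], cfgs[[k]]), expected[i, k],
                   tolerance = 1e-12)
})

test_that("psaIntensity rejects non-finite input", {
  expect_error(psaIntensity(c(1, NA, 0, 0), canonicalPSAConfigs()$Ih),
               "finite")
  expect_error(psaIntensity(c(1, Inf, 0, 0), canonicalPSAConfigs()$Ih),
               "finite")
})

test_that("PSAConfig validity pins canonical labels to their retardances", {
  expect_error(psaConfig(0, 0, label = "Irc"), "requires retardances")
  expect_s4_class(psaConfig(0.3, 1.2, label = "custom"), "PSAConfig")
})

test_that("illumination after the generator polarizer is as designed", {
  expect_equal(illuminationAfterPSG(intensity0 = 2), c(1, 0, 1, 0),
               tolerance = 1e-14)
  expect_equal(illuminationAfterPSG(intensity0 = 0), c(0, 0, 0, 0),
               tolerance = 1e-14)
  g0 <- instrumentGeometry(polarizer1Axis = 0)
  expect_equal(illuminationAfterPSG(g0, 2), c(1, 1, 0, 0),
               tolerance = 1e-14)
  expect_error(illuminationAfterPSG(intensity0 = -1), "nonnegative")
})

test_that("default instrument geometry matches the modeled microscope", {
  g <- instrumentGeometry()
  expect_equal(g@polarizer1Axis, 45)
  expect_equal(g@polarizer2Axis, 0)
  expect_equal(g@lcvr1FastAxis, 0)
  expect_equal(g@lcvr2FastAxis, 45)
})
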