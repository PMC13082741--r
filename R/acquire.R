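## Forward simulation of the four-analyzer acquisition sequence: for every
## pixel and band, exit Stokes = sample Mueller x illumination, detected
## intensity = first Mueller row of the analyzer arm applied to the exit
## light. The per-pixel sample model (transmittance, depolarizer, retarder)
## is applied with vectorized closed forms; equality with the materialized
## per-pixel Mueller product is checked in the test suite.

## Exit Stokes planes (4 arrays r x c x b) for a scene under an illumination
## Stokes vector per band (4 x nb matrix, columns = bands).
.sceneExitStokes <- function(scene, illum) {
  d <- dim(scene@transmittance)
  nr <- d[1]; nc <- d[2]; nb <- d[3]
  t <- scene@transmittance
  dp <- scene@depol
  a2 <- 2 * scene@retAxis * pi / 180
  c2a <- cos(a2); s2a <- sin(a2)            # r x c, recycled over bands
  cd <- cos(scene@retardance); sd <- sin(scene@retardance)

  e0 <- array(0, d); e1 <- array(0, d); e2 <- array(0, d); e3 <- array(0, d)
  for (b in seq_len(nb)) {
    s_in <- illum[, b]
    ## isotropic partial depolarizer diag(1, d, d, d)
    s0 <- array(s_in[1], c(nr, nc))
    s1 <- dp[, , b] * s_in[2]
    s2 <- dp[, , b] * s_in[3]
    s3 <- dp[, , b] * s_in[4]
    ## linear retarder at per-pixel axis: rotate into the fast-axis frame,
    ## apply the (S2, S3) rotation block [[cd, -sd], [sd, cd]], rotate back
    s1r <- c2a * s1 + s2a * s2
    s2r <- -s2a * s1 + c2a * s2
    s2p <- cd * s2r - sd * s3
    s3p <- sd * s2r + cd * s3
    s1o <- c2a * s1r - s2a * s2p
    s2o <- s2a * s1r + c2a * s2p
    tb <- t[, , b]
    e0[, , b] <- tb * s0
    e1[, , b] <- tb * s1o
    e2[, , b] <- tb * s2o
    e3[, , b] <- tb * s3p
  }
  list(s0 = e0, s1 = e1, s2 = e2, s3 = e3)
}

#' Simulate the four-analyzer acquisition of a scene
#'
#' Passes polarized illumination (unpolarized source through the generator
#' polarizer) through every scene pixel's sample Mueller matrix, detects the
#' intensity behind each of the four canonical analyzer configurations, and
#' applies the requested measurement noise. With \code{noiseModel$type =
#' "none"} the result is bit-reproducible; with noise it is a pure function
#' of (scene, geometry, noise model, seed).
#'
#' @param scene a \linkS4class{SampleScene}
#' @param geom an \linkS4class{InstrumentGeometry}
#' @param noiseModel list(type = "none"|"gaussian"|"poisson", sd, scale);
#'   \code{NULL} uses the noise model stored in the scene's phantom spec
#'   (or none). Gaussian sigma is \code{sd} times the full scale (maximum
#'   noiseless intensity over the four stacks); Poisson draws counts at
#'   \code{scale} counts per intensity unit.
#' @param seed integer seed for the noise draw (required when noise is on)
#' @param intensity0 unpolarized source intensity before the generator
#'   polarizer; flat across bands
#' @return an \linkS4class{AnalyzerStack}
#' @examples
#' sc <- generatePhantom(phantomSpec(imageSize = 64, nCellsPerClass = 1,
#'                                   seed = 3))
#' stk <- simulateAcquisition(sc, noiseModel = list(type = "none"))
#' @export
simulateAcquisition <- function(scene, geom = instrumentGeometry(),
                                noiseModel = NULL, seed = NULL,
                                intensity0 = 1) {
  stopifnot(is(scene, "SampleScene"), is(geom, "InstrumentGeometry"))
  validObject(scene)
  if (is.null(noiseModel)) {
    sp <- scene@metadata$spec
    noiseModel <- if (is(sp, "PhantomSpec")) sp@noiseModel
                  else list(type = "none")
  }
  if (noiseModel$type != "none" && is.null(seed))
    stop("a seed is required when the noise model is stochastic",
         call. = FALSE)

  nb <- nBands(scene)
  sIll <- illuminationAfterPSG(geom, intensity0)
  illum <- matrix(sIll, 4, nb)              # flat illumination spectrum
  exitS <- .sceneExitStokes(scene, illum)

  cfgs <- canonicalPSAConfigs()
  planes <- lapply(cfgs, function(cfg) {
    w <- psaMueller(cfg, geom)[1, ]
    w[1] * exitS$s0 + w[2] * exitS$s1 + w[3] * exitS$s2 + w[4] * exitS$s3
  })

  if (noiseModel$type != "none") {
    fullScale <- max(vapply(planes, max, numeric(1)))
    planes <- withSeed(seed, lapply(planes, function(p) {
      switch(noiseModel$type,
        gaussian = p + stats::rnorm(length(p),
                                    sd = noiseModel$sd * fullScale),
        poisson = {
          sc <- noiseModel$scale
          array(stats::rpois(length(p), pmax(p, 0) * sc) / sc, dim(p))
        })
    }))
    planes <- lapply(planes, function(p) array(p, dim(exitS$s0)))
  }

  analyzerStack(planes$Ih, planes$Iv, planes$I45, planes$Irc,
                wavelengths = wavelengths(scene),
                metadata = list(geometry = geom, noiseModel = noiseModel,
                                seed = seed, intensity0 = intensity0,
                                mode = "PHSI"))
}

`%||%` <- function(a, b) if (is.null(a)) b else a
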