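## Hyperspectral-to-RGB synthesis: collapse a data cube to three channels by
## weighting bands with eye-like spectral response curves, then normalize
## for display.

## Piecewise (two-sigma) Gaussian lobe, the standard analytic approximation
## form for the CIE 1931 color matching functions.
.cieLobe <- function(wl, alpha, mu, sigmaL, sigmaR) {
  s <- ifelse(wl < mu, sigmaL, sigmaR)
  alpha * exp(-0.5 * ((wl - mu) / s)^2)
}

#' Build eye-like spectral response curves
#'
#' Analytic Gaussian-mixture approximations of the CIE 1931 color matching
#' functions (multi-lobe piecewise Gaussians), evaluated on the cube's band
#' grid, clipped to nonnegative and normalized to unit sum per curve. The
#' red curve is bimodal (it keeps the short-wavelength lobe of the x-bar
#' function); the green curve peaks in the 530-570 nm range and the blue
#' curve near 450 nm.
#'
#' @param wavelengths strictly increasing band grid in nm, within
#'   [400, 800]
#' @return a \linkS4class{SpectralResponse}
#' @examples
#' resp <- buildDefaultResponse(seq(470, 750, 10))
#' sum(resp@g)   # 1
#' @export
buildDefaultResponse <- function(wavelengths) {
  wl <- as.numeric(wavelengths)
  if (length(wl) < 1 || any(!is.finite(wl)) ||
      (length(wl) > 1 && any(diff(wl) <= 0)))
    stop("wavelengths must be a strictly increasing finite grid",
         call. = FALSE)
  if (min(wl) < 400 || max(wl) > 800)
    stop("supported grid is 400-800 nm; got ",
         min(wl), "-", max(wl), " nm", call. = FALSE)
  r <- .cieLobe(wl, 1.056, 599.8, 37.9, 31.0) +
       .cieLobe(wl, 0.362, 442.0, 16.0, 26.7) -
       .cieLobe(wl, 0.065, 501.1, 20.4, 26.2)
  g <- .cieLobe(wl, 0.821, 568.8, 46.9, 40.5) +
       .cieLobe(wl, 0.286, 530.9, 16.3, 31.1)
  b <- .cieLobe(wl, 1.217, 437.0, 11.8, 36.0) +
       .cieLobe(wl, 0.681, 459.0, 26.0, 13.8)
  norm1 <- function(x) { x <- pmax(x, 0); x / sum(x) }
  new("SpectralResponse", wavelengths = wl, r = norm1(r), g = norm1(g),
      b = norm1(b))
}

#' Resample response curves to a cube's band grid
#'
#' Linear interpolation of each curve onto the target grid, followed by
#' renormalization to unit sum.
#'
#' @param response a \linkS4class{SpectralResponse}
#' @param wavelengths target band grid in nm
#' @return a \linkS4class{SpectralResponse} on the target grid
#' @export
resampleResponse <- function(response, wavelengths) {
  stopifnot(is(response, "SpectralResponse"))
  wl <- as.numeric(wavelengths)
  rs <- function(y) {
    v <- stats::approx(response@wavelengths, y, xout = wl, rule = 2)$y
    v <- pmax(v, 0); v / sum(v)
  }
  new("SpectralResponse", wavelengths = wl, r = rs(response@r),
      g = rs(response@g), b = rs(response@b))
}

#' Render a cube plane as a synthetic RGB image
#'
#' Each output channel is the band-weighted sum of the plane against one
#' response curve; a display normalization then maps the channels into
#' [0, 1]. A signed plane (S1, S2, S3 can be negative) is first shifted
#' affinely to [0, 1] by its own min-max; the shift is recorded in the
#' provenance. NaN source pixels are flagged in the invalid mask and set to
#' 0, never propagated. The function is pure: the input cube is untouched.
#'
#' @param plane numeric array rows x cols x bands (a single matrix is
#'   treated as one band)
#' @param response a \linkS4class{SpectralResponse} on the same band grid
#'   (resampled automatically if its grid differs)
#' @param norm display normalization: \code{"percentile"} (default; robust
#'   per-channel scaling between the (100-p)th and pth percentiles, then
#'   clipped), \code{"per_channel"} (min-max per channel), \code{"global"}
#'   (joint min-max over the three channels), or \code{"none"} (raw channel
#'   sums)
#' @param p percentile for \code{norm = "percentile"}
#' @param planeName source plane name stored in the provenance
#' @return an \linkS4class{RGBImage}
#' @examples
#' wl <- seq(470, 750, 10)
#' cube <- array(runif(16 * 16 * 29), c(16, 16, 29))
#' img <- hsiToRGB(cube, buildDefaultResponse(wl), norm = "per_channel")
#' @export
hsiToRGB <- function(plane, response, norm = c("percentile", "per_channel",
                                               "global", "none"),
                     p = 99, planeName = "cube") {
  norm <- match.arg(norm)
  stopifnot(is(response, "SpectralResponse"))
  if (is.matrix(plane)) plane <- array(plane, c(dim(plane), 1L))
  stopifnot(length(dim(plane)) == 3L)
  nb <- dim(plane)[3]
  if (length(response@wavelengths) != nb)
    stop("response has ", length(response@wavelengths), " bands but the ",
         "plane has ", nb, "; resample with resampleResponse() first",
         call. = FALSE)

  nr <- dim(plane)[1]; nc <- dim(plane)[2]
  invalid <- apply(is.na(plane), c(1, 2), any)
  work <- plane
  work[is.na(work)] <- 0

  shift <- c(offset = 0, scale = 1)
  finiteRange <- range(work)
  if (finiteRange[1] < 0) {
    span <- diff(finiteRange)
    if (span == 0) span <- 1
    work <- (work - finiteRange[1]) / span
    shift <- c(offset = finiteRange[1], scale = span)
  }

  flat <- matrix(work, nr * nc, nb)
  ch <- flat %*% cbind(response@r, response@g, response@b)
  ch[invalid, ] <- 0

  normalize <- function(ch) {
    switch(norm,
      none = ch,
      global = {
        rng <- range(ch)
        if (diff(rng) == 0) ch * 0 else (ch - rng[1]) / diff(rng)
      },
      per_channel = apply(ch, 2, function(x) {
        rng <- range(x)
        if (diff(rng) == 0) x * 0 else (x - rng[1]) / diff(rng)
      }),
      percentile = apply(ch, 2, function(x) {
        lo <- stats::quantile(x, (100 - p) / 100, names = FALSE)
        hi <- stats::quantile(x, p / 100, names = FALSE)
        if (hi == lo) x * 0 else pmax(0, pmin(1, (x - lo) / (hi - lo)))
      }))
  }
  ch <- normalize(ch)

  new("RGBImage", rgb = array(ch, c(nr, nc, 3L)), invalidMask = invalid,
      provenance = list(plane = planeName, norm = norm, percentile = p,
                        signedShift = shift))
}

#' Write an RGB image as PNG
#'
#' Writes the rendered channels as an 8-bit PNG; the provenance list is
#' written alongside as \code{<path>.json} so the rendering is traceable to
#' its source plane and normalization.
#'
#' @param img an \linkS4class{RGBImage} (must be normalized to [0, 1])
#' @param path output file path
#' @return the path, invisibly
#' @export
writeRGBImage <- function(img, path) {
  stopifnot(is(img, "RGBImage"))
  x <- pmin(pmax(img@rgb, 0), 1)   # array first: pmax/pmin keep its dim
  png::writePNG(x, path)
  jsonlite::write_json(img@provenance, paste0(path, ".json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(path)
}
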