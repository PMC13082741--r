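## Stokes reconstruction from the four analyzer intensities and the derived
## degree-of-polarization maps, with explicit handling of the degeneracies a
## noisy reconstruction produces (dark pixels, DOP > 1).

#' Reconstruct Stokes parameters from a four-analyzer stack
#'
#' Elementwise data reduction:
#' \deqn{S_0 = I_h + I_v,\quad S_1 = I_h - I_v,\quad
#'       S_2 = 2 I_{45} - (I_h + I_v),\quad S_3 = 2 I_{rc} - (I_h + I_v)}
#' No physicality clipping is applied here; noisy input can yield vectors
#' with polarized intensity above S0 (inspect with
#' \code{\link{physicalityReport}}).
#'
#' @param stack an \linkS4class{AnalyzerStack}
#' @return a \linkS4class{StokesCube} on the same grid
#' @examples
#' stk <- analyzerStack(ih = matrix(1), iv = matrix(0),
#'                      i45 = matrix(0.5), irc = matrix(0.5),
#'                      wavelengths = 550)
#' cubePlane(computeStokes(stk), "S1")   # 1: horizontal linear light
#' @export
computeStokes <- function(stack) {
  stopifnot(is(stack, "AnalyzerStack"))
  validObject(stack)
  ih <- stack@ih; iv <- stack@iv
  s0 <- ih + iv
  new("StokesCube",
      s0 = s0, s1 = ih - iv, s2 = 2 * stack@i45 - s0,
      s3 = 2 * stack@irc - s0,
      wavelengths = stack@wavelengths,
      metadata = c(stack@metadata, list(reduction = "four-analyzer")))
}

#' Compute DOP, DOLP and DOCP maps
#'
#' Wherever S0 exceeds the floor:
#' \deqn{DOP = \sqrt{S_1^2 + S_2^2 + S_3^2} / S_0,\quad
#'       DOLP = \sqrt{S_1^2 + S_2^2} / S_0,\quad DOCP = |S_3| / S_0}
#' so that \eqn{DOP = \sqrt{DOLP^2 + DOCP^2}} holds identically. Pixels at
#' or below the floor are marked invalid and set to 0.
#'
#' @param cube a \linkS4class{StokesCube}
#' @param s0Floor validity floor on S0. The default \code{"auto"} uses
#'   1e-3 times the cube's 99th-percentile S0, masking dark background
#'   where the ratios are meaningless without hard-coding a detector unit.
#' @param clipPolicy what to do with values above 1 (noise artifacts):
#'   \code{"clip"} (default) clips to 1 and counts the clipped values,
#'   \code{"flag"} leaves values but stores the count, \code{"allow"}
#'   leaves values and does not count
#' @return a \linkS4class{DerivedCube}
#' @examples
#' stk <- analyzerStack(matrix(0.8), matrix(0.2), matrix(0.5), matrix(0.9),
#'                      wavelengths = 550)
#' dv <- computeDerived(computeStokes(stk))
#' cubePlane(dv, "DOP")
#' @export
computeDerived <- function(cube, s0Floor = "auto",
                           clipPolicy = c("clip", "flag", "allow")) {
  stopifnot(is(cube, "StokesCube"))
  clipPolicy <- match.arg(clipPolicy)
  s0 <- cube@s0
  if (identical(s0Floor, "auto"))
    s0Floor <- 1e-3 * stats::quantile(s0, 0.99, names = FALSE)
  stopifnot(is.numeric(s0Floor), s0Floor >= 0)

  valid <- s0 > s0Floor
  safe0 <- ifelse(valid, s0, 1)
  lin2 <- cube@s1^2 + cube@s2^2
  dolp <- sqrt(lin2) / safe0
  docp <- abs(cube@s3) / safe0
  dop <- sqrt(lin2 + cube@s3^2) / safe0
  dop[!valid] <- 0; dolp[!valid] <- 0; docp[!valid] <- 0

  nClip <- 0L
  if (clipPolicy != "allow")
    nClip <- sum(dop[valid] > 1) + sum(dolp[valid] > 1) +
      sum(docp[valid] > 1)
  if (clipPolicy == "clip") {
    dop <- pmin(dop, 1); dolp <- pmin(dolp, 1); docp <- pmin(docp, 1)
  }

  new("DerivedCube", dop = dop, dolp = dolp, docp = docp,
      maskValid = valid, wavelengths = cube@wavelengths,
      clippedCount = as.integer(nClip),
      metadata = c(cube@metadata,
                   list(s0Floor = s0Floor, clipPolicy = clipPolicy)))
}

#' Physical-realizability report of a Stokes cube
#'
#' Counts, per band and overall, the pixels whose polarized intensity
#' sqrt(S1^2+S2^2+S3^2) exceeds S0 — impossible for physical light, expected
#' in small numbers for noisy reconstructions. Pure inspection; nothing is
#' modified.
#'
#' @param cube a \linkS4class{StokesCube}
#' @param tol violations smaller than \code{tol} (absolute, in intensity
#'   units) are ignored as floating-point noise
#' @return list with \code{perBand} (data.frame: band, wavelength,
#'   nViolations, fraction, maxExcess), \code{nTotal}, \code{fractionTotal}
#'   and \code{maxExcess}
#' @export
physicalityReport <- function(cube, tol = 0) {
  stopifnot(is(cube, "StokesCube"))
  nb <- nBands(cube)
  npx <- prod(spatialDims(cube))
  excess <- sqrt(cube@s1^2 + cube@s2^2 + cube@s3^2) - cube@s0
  perBand <- data.frame(
    band = seq_len(nb), wavelength = cube@wavelengths,
    nViolations = vapply(seq_len(nb), function(b)
      sum(excess[, , b] > tol), integer(1)),
    maxExcess = vapply(seq_len(nb), function(b)
      max(excess[, , b], 0), numeric(1)))
  perBand$fraction <- perBand$nViolations / npx
  list(perBand = perBand[, c("band", "wavelength", "nViolations",
                             "fraction", "maxExcess")],
       nTotal = sum(perBand$nViolations),
       fractionTotal = sum(perBand$nViolations) / (npx * nb),
       maxExcess = max(perBand$maxExcess))
}
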