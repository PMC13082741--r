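## Mueller-calculus building blocks for the polarization state generator and
## analyzer. Stokes vectors are plain length-4 numerics (S0, S1, S2, S3) with
## S3 > 0 for right-circular light; Mueller matrices are plain 4x4 numerics.
##
## Sign conventions (fixed so the four canonical LCVR settings realize the
## Ih/Iv/I45/Irc analyzers exactly):
##   * frame rotation by angle a uses cos(2a), +sin(2a) in row 2;
##   * a retarder with fast axis at 0 and retardance delta maps
##     (S2, S3) -> (S2 cos d - S3 sin d, S2 sin d + S3 cos d),
##     i.e. a quarter-wave plate at 0 deg turns +45-linear into
##     right-circular (+S3).
## Both are cross-checked against a Jones-calculus oracle in the test suite.

.deg2 <- function(angle) 2 * angle * pi / 180

#' Validate a Stokes vector
#'
#' Checks the length-4 numeric form and, optionally, physical realizability
#' (S0 >= 0 and polarized intensity not exceeding S0).
#'
#' @param s numeric length-4 vector (S0, S1, S2, S3)
#' @param physical if TRUE also require S0 >= 0 and
#'   sqrt(S1^2+S2^2+S3^2) <= S0 (up to \code{tol})
#' @param tol tolerance for the realizability check
#' @return the vector, invisibly; errors on violation
#' @export
stokesVector <- function(s, physical = FALSE, tol = 1e-9) {
  if (length(s) != 4L || !is.numeric(s) || any(!is.finite(s)))
    stop("a Stokes vector is 4 finite numbers (S0, S1, S2, S3)",
         call. = FALSE)
  if (physical) {
    if (s[1] < 0) stop("physical light requires S0 >= 0", call. = FALSE)
    if (sqrt(sum(s[2:4]^2)) > s[1] * (1 + tol) + tol)
      stop("polarized intensity exceeds S0: not physically realizable",
           call. = FALSE)
  }
  invisible(s)
}

#' Mueller matrix of a Stokes frame rotation
#'
#' Rotates the polarization reference frame by \code{angle}; acts on the
#' (S1, S2) pair with the doubled angle and leaves S0, S3 unchanged.
#' \code{rotationMueller(a) \%*\% rotationMueller(-a)} is the identity.
#'
#' @param angle rotation angle in degrees
#' @return 4x4 Mueller matrix
#' @examples
#' rotationMueller(0)                      # identity
#' rotationMueller(45) %*% c(1, 1, 0, 0)   # -> (1, 0, -1, 0)
#' @export
rotationMueller <- function(angle) {
  stopifnot(is.finite(angle))
  a <- .deg2(angle)
  c2 <- cos(a); s2 <- sin(a)
  matrix(c(1,   0,  0, 0,
           0,  c2, s2, 0,
           0, -s2, c2, 0,
           0,   0,  0, 1), 4, 4, byrow = TRUE)
}

#' Mueller matrix of an ideal linear polarizer
#'
#' Transmissive axis at \code{axis} degrees. Transmits half of unpolarized
#' light; any transmitted beam is fully polarized.
#'
#' @param axis transmissive axis in degrees
#' @return 4x4 Mueller matrix
#' @examples
#' linearPolarizer(0) %*% c(1, 0, 0, 0)    # -> (0.5, 0.5, 0, 0)
#' @export
linearPolarizer <- function(axis) {
  stopifnot(is.finite(axis))
  p0 <- 0.5 * matrix(c(1, 1, 0, 0,
                       1, 1, 0, 0,
                       0, 0, 0, 0,
                       0, 0, 0, 0), 4, 4, byrow = TRUE)
  rotationMueller(-axis) %*% p0 %*% rotationMueller(axis)
}

#' Mueller matrix of an ideal linear retarder
#'
#' A variable retarder (LCVR model) with the given fast axis and phase
#' retardance. Retardance 0 or 2*pi gives the identity; S0 is never changed.
#'
#' @param fastAxis fast axis orientation in degrees
#' @param retardance phase retardance in radians (pi/2 = quarter wave,
#'   pi = half wave)
#' @return 4x4 Mueller matrix
#' @examples
#' variableRetarder(0, pi / 2) %*% c(1, 0, 1, 0)   # -> (1, 0, 0, 1)
#' @export
variableRetarder <- function(fastAxis, retardance) {
  stopifnot(is.finite(fastAxis), is.finite(retardance))
  cd <- cos(retardance); sd <- sin(retardance)
  r0 <- matrix(c(1, 0,  0,   0,
                 0, 1,  0,   0,
                 0, 0,  cd, -sd,
                 0, 0,  sd,  cd), 4, 4, byrow = TRUE)
  rotationMueller(-fastAxis) %*% r0 %*% rotationMueller(fastAxis)
}

#' Mueller matrix of an isotropic partial depolarizer
#'
#' diag(1, d, d, d): scales the polarized part by the depolarization factor
#' d, so output DOP = d * input DOP.
#'
#' @param d depolarization factor in [0, 1] (1 = no depolarization)
#' @return 4x4 Mueller matrix
#' @export
partialDepolarizer <- function(d) {
  stopifnot(is.finite(d), d >= 0, d <= 1)
  diag(c(1, d, d, d))
}

#' Full Mueller matrix of the polarization state analyzer
#'
#' Polarizer 2 composed with the two LCVRs at one retardance configuration:
#' \code{P2 \%*\% LCVR2 \%*\% LCVR1}.
#'
#' @param cfg a \linkS4class{PSAConfig}
#' @param geom an \linkS4class{InstrumentGeometry}
#' @return 4x4 Mueller matrix of the whole analyzer arm
#' @export
psaMueller <- function(cfg, geom = instrumentGeometry()) {
  stopifnot(is(cfg, "PSAConfig"), is(geom, "InstrumentGeometry"))
  linearPolarizer(geom@polarizer2Axis) %*%
    variableRetarder(geom@lcvr2FastAxis, cfg@retardance2) %*%
    variableRetarder(geom@lcvr1FastAxis, cfg@retardance1)
}

#' Detected intensity behind the analyzer
#'
#' Total intensity (S0 component) after the sample light passes LCVR 1,
#' LCVR 2 and polarizer 2. For the canonical configurations this equals
#' 0.5*(S0+S1) for Ih, 0.5*(S0-S1) for Iv, 0.5*(S0+S2) for I45 and
#' 0.5*(S0+S3) for Irc.
#'
#' @param s Stokes vector entering the analyzer arm
#' @param cfg a \linkS4class{PSAConfig}
#' @param geom an \linkS4class{InstrumentGeometry}
#' @return scalar detected intensity
#' @examples
#' cfgs <- canonicalPSAConfigs()
#' psaIntensity(c(1, 1, 0, 0), cfgs$Ih)   # 1
#' psaIntensity(c(1, 1, 0, 0), cfgs$Iv)   # 0
#' psaIntensity(c(1, 0, 0, 1), cfgs$Irc)  # 1
#' @export
psaIntensity <- function(s, cfg, geom = instrumentGeometry()) {
  stokesVector(s)
  drop(psaMueller(cfg, geom)[1, ] %*% s)
}

#' Illumination Stokes vector behind the generator polarizer
#'
#' An unpolarized source of the given intensity passed through polarizer 1;
#' with the default 45-degree axis this is 0.5*intensity0*(1, 0, 1, 0).
#'
#' @param geom an \linkS4class{InstrumentGeometry}
#' @param intensity0 source intensity (>= 0), arbitrary detector units
#' @return Stokes vector of the light reaching the sample
#' @examples
#' illuminationAfterPSG(intensity0 = 2)    # (1, 0, 1, 0)
#' @export
illuminationAfterPSG <- function(geom = instrumentGeometry(),
                                 intensity0 = 1) {
  stopifnot(is(geom, "InstrumentGeometry"))
  if (!is.finite(intensity0) || intensity0 < 0)
    stop("intensity0 must be a finite nonnegative scalar", call. = FALSE)
  drop(linearPolarizer(geom@polarizer1Axis) %*% c(intensity0, 0, 0, 0))
}
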