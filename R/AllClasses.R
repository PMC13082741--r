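## Central S4 containers of the pipeline. Raw Mueller matrices and Stokes
## vectors are plain base-R numerics (see mueller.R for validators); the
## classes below hold the image-sized data with shape/physicality checks.

.checkCubeArray <- function(x, what, nb = NULL) {
  if (!is.array(x) || length(dim(x)) != 3L)
    return(sprintf("'%s' must be a rows x cols x bands array", what))
  if (!is.null(nb) && dim(x)[3] != nb)
    return(sprintf("'%s' has %d bands, expected %d", what, dim(x)[3], nb))
  NULL
}

.checkWavelengths <- function(wl, nb = NULL) {
  msg <- NULL
  if (length(wl) == 0L) msg <- c(msg, "empty wavelength grid")
  if (anyNA(wl) || any(!is.finite(wl))) msg <- c(msg, "non-finite wavelengths")
  if (length(wl) > 1L && any(diff(wl) <= 0))
    msg <- c(msg, "wavelengths must be strictly increasing")
  if (!is.null(nb) && length(wl) != nb)
    msg <- c(msg, sprintf("%d wavelengths for %d bands", length(wl), nb))
  msg
}

#' Instrument geometry of the polarization optics
#'
#' Orientations (degrees, counterclockwise looking toward the source) of the
#' four polarization elements: the illumination-side polarizer (polarization
#' state generator), the two liquid crystal variable retarders, and the
#' detection-side polarizer. The defaults are the instrument geometry the
#' pipeline models: polarizer 1 at 45 degrees, polarizer 2 at 0 degrees,
#' LCVR 1 fast axis at 0 degrees, LCVR 2 fast axis at 45 degrees.
#'
#' @slot polarizer1Axis transmissive axis of the generator polarizer (deg)
#' @slot polarizer2Axis transmissive axis of the analyzer polarizer (deg)
#' @slot lcvr1FastAxis fast axis of LCVR 1 (deg)
#' @slot lcvr2FastAxis fast axis of LCVR 2 (deg)
#' @export
setClass("InstrumentGeometry",
  representation(polarizer1Axis = "numeric", polarizer2Axis = "numeric",
                 lcvr1FastAxis = "numeric", lcvr2FastAxis = "numeric"),
  prototype(polarizer1Axis = 45, polarizer2Axis = 0,
            lcvr1FastAxis = 0, lcvr2FastAxis = 45),
  validity = function(object) {
    v <- c(object@polarizer1Axis, object@polarizer2Axis,
           object@lcvr1FastAxis, object@lcvr2FastAxis)
    if (length(v) != 4L || any(!is.finite(v))) "all axes must be finite scalars"
    else TRUE
  })

#' Construct an instrument geometry
#'
#' @param polarizer1Axis,polarizer2Axis,lcvr1FastAxis,lcvr2FastAxis element
#'   orientations in degrees; defaults are the modeled microscope's values.
#' @return an \linkS4class{InstrumentGeometry}
#' @examples
#' instrumentGeometry()                      # the default microscope
#' instrumentGeometry(polarizer1Axis = 0)    # horizontal illumination
#' @export
instrumentGeometry <- function(polarizer1Axis = 45, polarizer2Axis = 0,
                               lcvr1FastAxis = 0, lcvr2FastAxis = 45) {
  new("InstrumentGeometry",
      polarizer1Axis = polarizer1Axis, polarizer2Axis = polarizer2Axis,
      lcvr1FastAxis = lcvr1FastAxis, lcvr2FastAxis = lcvr2FastAxis)
}

#' One polarization state analyzer configuration
#'
#' A pair of LCVR retardances plus the analyzer label it realizes. The four
#' canonical configurations (see \code{\link{canonicalPSAConfigs}}) are
#' (0, 0) for Ih, (0, pi) for Iv, (pi/2, pi/2) for I45 and (0, pi/2) for Irc.
#'
#' @slot retardance1 LCVR 1 retardance, radians
#' @slot retardance2 LCVR 2 retardance, radians
#' @slot label analyzer label, one of "Ih", "Iv", "I45", "Irc" (or a free
#'   label for non-canonical settings)
#' @export
setClass("PSAConfig",
  representation(retardance1 = "numeric", retardance2 = "numeric",
                 label = "character"),
  validity = function(object) {
    if (!is.finite(object@retardance1) || !is.finite(object@retardance2))
      return("retardances must be finite")
    canon <- list(Ih = c(0, 0), Iv = c(0, pi), I45 = c(pi / 2, pi / 2),
                  Irc = c(0, pi / 2))
    lbl <- object@label
    if (lbl %in% names(canon)) {
      want <- canon[[lbl]]
      got <- c(object@retardance1, object@retardance2)
      if (max(abs(got - want)) > 1e-12)
        return(sprintf("label '%s' requires retardances (%g, %g)",
                       lbl, want[1], want[2]))
    }
    TRUE
  })

#' @rdname PSAConfig-class
#' @param retardance1,retardance2 LCVR retardances in radians
#' @param label analyzer label
#' @return a \linkS4class{PSAConfig}
#' @export
psaConfig <- function(retardance1, retardance2, label = "custom") {
  new("PSAConfig", retardance1 = retardance1, retardance2 = retardance2,
      label = label)
}

#' The four canonical analyzer configurations
#'
#' Retardance pairs that turn the LCVR pair plus fixed polarizer into a
#' horizontal (Ih), vertical (Iv), 45-degree (I45) and right-circular (Irc)
#' analyzer, in that order.
#'
#' @return named list of four \linkS4class{PSAConfig} objects
#' @examples
#' names(canonicalPSAConfigs())
#' @export
canonicalPSAConfigs <- function() {
  list(Ih  = psaConfig(0, 0, "Ih"),
       Iv  = psaConfig(0, pi, "Iv"),
       I45 = psaConfig(pi / 2, pi / 2, "I45"),
       Irc = psaConfig(0, pi / 2, "Irc"))
}

#' Four-analyzer intensity stack
#'
#' The four co-registered intensity cubes measured through the canonical
#' analyzers, sharing one spatial grid and one spectral axis. This is the raw
#' input to Stokes reconstruction. In polarized-light (RGB) mode the three
#' "bands" are broadband color channels; \code{wavelengths} then holds
#' nominal channel centers and \code{metadata$mode} is \code{"PLI"}.
#'
#' @slot ih,iv,i45,irc numeric arrays, rows x cols x bands, detector units
#' @slot wavelengths band centers in nm
#' @slot metadata list: geometry, acquisition provenance, noise description
#' @export
setClass("AnalyzerStack",
  representation(ih = "array", iv = "array", i45 = "array", irc = "array",
                 wavelengths = "numeric", metadata = "list"),
  validity = function(object) {
    msg <- NULL
    d <- dim(object@ih)
    for (pl in c("iv", "i45", "irc")) {
      dd <- dim(slot(object, pl))
      if (!identical(d, dd))
        msg <- c(msg, sprintf(
          "plane '%s' has shape (%s), expected (%s) from 'ih'",
          pl, paste(dd, collapse = "x"), paste(d, collapse = "x")))
    }
    msg <- c(msg, .checkCubeArray(object@ih, "ih"),
             .checkWavelengths(object@wavelengths, dim(object@ih)[3]))
    for (pl in c("ih", "iv", "i45", "irc"))
      if (any(!is.finite(slot(object, pl))))
        msg <- c(msg, sprintf("non-finite intensities in '%s'", pl))
    if (is.null(msg)) TRUE else msg
  })

#' Construct an analyzer stack
#'
#' @param ih,iv,i45,irc intensity arrays (rows x cols x bands); 2-D matrices
#'   are promoted to single-band cubes
#' @param wavelengths band centers in nm
#' @param metadata free-form provenance list
#' @return an \linkS4class{AnalyzerStack}
#' @export
analyzerStack <- function(ih, iv, i45, irc, wavelengths, metadata = list()) {
  as3d <- function(x) if (is.matrix(x)) array(x, c(dim(x), 1L)) else x
  new("AnalyzerStack", ih = as3d(ih), iv = as3d(iv), i45 = as3d(i45),
      irc = as3d(irc), wavelengths = as.numeric(wavelengths),
      metadata = metadata)
}

#' Reconstructed Stokes parameter cube
#'
#' Per-pixel, per-band Stokes parameters S0..S3 on the acquisition grid.
#' By construction from \code{\link{computeStokes}}, \code{s0 = ih + iv}
#' elementwise. No physicality clipping is applied at this stage; noisy
#' reconstructions may carry sqrt(S1^2+S2^2+S3^2) > S0 (see
#' \code{\link{physicalityReport}}).
#'
#' @slot s0,s1,s2,s3 numeric arrays, rows x cols x bands
#' @slot wavelengths band centers in nm
#' @slot metadata provenance list
#' @export
setClass("StokesCube",
  representation(s0 = "array", s1 = "array", s2 = "array", s3 = "array",
                 wavelengths = "numeric", metadata = "list"),
  validity = function(object) {
    msg <- NULL
    d <- dim(object@s0)
    for (pl in c("s1", "s2", "s3"))
      if (!identical(dim(slot(object, pl)), d))
        msg <- c(msg, sprintf("plane '%s' shape differs from 's0'", pl))
    msg <- c(msg, .checkCubeArray(object@s0, "s0"),
             .checkWavelengths(object@wavelengths, d[3]))
    if (is.null(msg)) TRUE else msg
  })

#' Degree-of-polarization cube
#'
#' Per-pixel, per-band DOP, DOLP and DOCP maps in [0, 1] at valid pixels,
#' plus the validity mask (pixels whose S0 exceeded the floor) and the count
#' of values clipped back into [0, 1] under the clip policy.
#'
#' @slot dop,dolp,docp numeric arrays in [0, 1] at valid pixels
#' @slot maskValid logical array, TRUE where S0 > floor
#' @slot wavelengths band centers in nm
#' @slot clippedCount integer, number of values clipped to 1
#' @slot metadata provenance list (records s0 floor and clip policy)
#' @export
setClass("DerivedCube",
  representation(dop = "array", dolp = "array", docp = "array",
                 maskValid = "array", wavelengths = "numeric",
                 clippedCount = "integer", metadata = "list"),
  validity = function(object) {
    msg <- NULL
    d <- dim(object@dop)
    for (pl in c("dolp", "docp", "maskValid"))
      if (!identical(dim(slot(object, pl)), d))
        msg <- c(msg, sprintf("plane '%s' shape differs from 'dop'", pl))
    msg <- c(msg, .checkWavelengths(object@wavelengths, d[3]))
    if (isTRUE(object@metadata$clipPolicy == "clip")) {
      v <- object@maskValid
      for (pl in c("dop", "dolp", "docp")) {
        x <- slot(object, pl)[v]
        if (length(x) && (min(x) < 0 || max(x) > 1 + 1e-12))
          msg <- c(msg, sprintf("'%s' outside [0,1] at valid pixels", pl))
      }
    }
    if (is.null(msg)) TRUE else msg
  })

#' Synthetic blood-smear scene
#'
#' Ground truth for the simulator: a compact parametric per-pixel sample
#' model (transmittance, isotropic depolarization factor, linear retardance
#' and its axis), per-pixel class labels, a cell-id map and per-cell records.
#' The full 4x4 sample Mueller matrix of any pixel is materialized by
#' \code{\link{sceneMueller}}.
#'
#' Label codes: 0 background, 1 granulocyte cytoplasm, 2 lymphocyte,
#' 3 monocyte cytoplasm, 4 nucleus, 5 granule.
#'
#' @slot wavelengths band centers in nm, within [400, 800]
#' @slot transmittance array rows x cols x bands, t in [0, 1]
#' @slot depol array rows x cols x bands, depolarization factor d in [0, 1]
#' @slot retardance matrix rows x cols, linear retardance in radians
#' @slot retAxis matrix rows x cols, retarder fast axis in degrees
#' @slot labels integer matrix of per-pixel class codes
#' @slot cellMap integer matrix of cell ids (0 = background)
#' @slot cellRecords data.frame: cellId, class, centroidRow, centroidCol,
#'   nPixels, depolMean
#' @slot metadata list incl. the generating \linkS4class{PhantomSpec}
#' @export
setClass("SampleScene",
  representation(wavelengths = "numeric", transmittance = "array",
                 depol = "array", retardance = "matrix", retAxis = "matrix",
                 labels = "matrix", cellMap = "matrix",
                 cellRecords = "data.frame", metadata = "list"),
  validity = function(object) {
    msg <- NULL
    d <- dim(object@transmittance)
    msg <- c(msg, .checkCubeArray(object@transmittance, "transmittance"),
             .checkCubeArray(object@depol, "depol", d[3]),
             .checkWavelengths(object@wavelengths, d[3]))
    if (min(object@wavelengths) < 400 || max(object@wavelengths) > 800)
      msg <- c(msg, "wavelengths must lie within [400, 800] nm")
    rng <- range(object@transmittance)
    if (rng[1] < 0 || rng[2] > 1) msg <- c(msg, "transmittance outside [0,1]")
    rng <- range(object@depol)
    if (rng[1] < 0 || rng[2] > 1) msg <- c(msg, "depol outside [0,1]")
    for (pl in c("retardance", "retAxis", "labels", "cellMap"))
      if (!identical(dim(slot(object, pl)), d[1:2]))
        msg <- c(msg, sprintf("'%s' shape differs from spatial grid", pl))
    cr <- object@cellRecords
    if (nrow(cr)) {
      counts <- table(factor(object@cellMap[object@cellMap > 0],
                             levels = cr$cellId))
      if (any(counts == 0)) msg <- c(msg, "a recorded cell has an empty mask")
    }
    if (is.null(msg)) TRUE else msg
  })

#' Phantom generation parameters
#'
#' Everything that determines a synthetic blood-smear field: geometry,
#' per-class cell counts and morphology knobs, the stain transmission curve,
#' per-class depolarization distributions, the measurement noise model and
#' the seed. The same spec and seed always generate the same scene.
#'
#' @slot imageSize integer c(rows, cols)
#' @slot nCellsPerClass named integer vector over
#'   c("granulocyte", "lymphocyte", "monocyte")
#' @slot cellRadiusRange numeric c(min, max) semi-axis range in pixels
#' @slot granuleDensity fraction of granulocyte pixels carrying a granule
#' @slot granuleDepolContrast amplitude of the granule depolarization
#'   texture, in [0, 1]
#' @slot surfaceTextureAmplitude amplitude of the smooth lymphocyte surface
#'   texture (depolarization and retardance), in [0, 1]
#' @slot nucleusLobedness 0 = round monocyte nucleus, 1 = strongly lobed
#' @slot classDepolMean named per-class mean depolarization factor
#' @slot classDepolSD between-cell standard deviation of the factor
#' @slot depolDispersion fractional linear decrease of depolarization across
#'   the band range (scattering falls with wavelength)
#' @slot stainTransmission list(baseline, depth, center, width): Gaussian
#'   absorption band giving the stain's transmission minimum (default center
#'   535 nm, within the 520-550 nm region typical of stained smears)
#' @slot stainUptakeSD between-cell SD of the multiplicative stain uptake
#'   factor (staining variability between cells)
#' @slot wavelengths simulation band grid in nm
#' @slot noiseModel list(type = "none"|"gaussian"|"poisson", sd = fraction
#'   of full scale for gaussian, scale = counts per unit for poisson)
#' @slot seed integer; fully determines the scene
#' @slot maxPlaceAttempts rejection-sampling budget per cell
#' @export
setClass("PhantomSpec",
  representation(imageSize = "integer", nCellsPerClass = "integer",
                 cellRadiusRange = "numeric", granuleDensity = "numeric",
                 granuleDepolContrast = "numeric",
                 surfaceTextureAmplitude = "numeric",
                 nucleusLobedness = "numeric", classDepolMean = "numeric",
                 classDepolSD = "numeric", depolDispersion = "numeric",
                 stainTransmission = "list", stainUptakeSD = "numeric",
                 wavelengths = "numeric",
                 noiseModel = "list", seed = "integer",
                 maxPlaceAttempts = "integer"),
  validity = function(object) {
    msg <- NULL
    if (length(object@imageSize) != 2L || any(object@imageSize < 8L))
      msg <- c(msg, "imageSize must be two integers >= 8")
    cls <- c("granulocyte", "lymphocyte", "monocyte")
    if (!all(cls %in% names(object@nCellsPerClass)))
      msg <- c(msg, "nCellsPerClass must name granulocyte/lymphocyte/monocyte")
    if (any(object@nCellsPerClass < 0L)) msg <- c(msg, "negative cell count")
    unit <- c(granule = object@granuleDensity,
              contrast = object@granuleDepolContrast,
              texture = object@surfaceTextureAmplitude,
              lobed = object@nucleusLobedness,
              depolSD = object@classDepolSD)
    if (any(unit < 0 | unit > 1))
      msg <- c(msg, "contrasts/amplitudes must lie in [0, 1]")
    if (any(object@classDepolMean < 0 | object@classDepolMean > 1))
      msg <- c(msg, "classDepolMean must lie in [0, 1]")
    if (length(object@cellRadiusRange) != 2L ||
        any(object@cellRadiusRange <= 0) ||
        diff(object@cellRadiusRange) < 0)
      msg <- c(msg, "cellRadiusRange must be increasing positive pair")
    msg <- c(msg, .checkWavelengths(object@wavelengths))
    if (!object@noiseModel$type %in% c("none", "gaussian", "poisson"))
      msg <- c(msg, "noiseModel$type must be none/gaussian/poisson")
    if (is.null(msg)) TRUE else msg
  })

#' Spectral response curves for RGB synthesis
#'
#' Three nonnegative per-band weight curves (R, G, B) on a wavelength grid;
#' each curve sums to one so a spectrally flat cube renders gray.
#'
#' @slot wavelengths band grid in nm
#' @slot r,g,b nonnegative weights per band
#' @export
setClass("SpectralResponse",
  representation(wavelengths = "numeric", r = "numeric", g = "numeric",
                 b = "numeric"),
  validity = function(object) {
    msg <- .checkWavelengths(object@wavelengths)
    n <- length(object@wavelengths)
    for (ch in c("r", "g", "b")) {
      w <- slot(object, ch)
      if (length(w) != n) msg <- c(msg, sprintf("'%s' length != bands", ch))
      if (any(w < 0)) msg <- c(msg, sprintf("negative weights in '%s'", ch))
      if (all(w == 0)) msg <- c(msg, sprintf("'%s' has no positive weight", ch))
    }
    if (is.null(msg)) TRUE else msg
  })

#' Synthesized RGB image
#'
#' A three-channel rendering of one cube plane. Values are in [0, 1] after
#' display normalization; with \code{norm = "none"} the raw channel sums are
#' kept and may exceed [0, 1]. Pixels that were NaN in the source cube are
#' flagged in \code{invalidMask} and set to 0 in the image.
#'
#' @slot rgb numeric array rows x cols x 3
#' @slot invalidMask logical matrix of NaN-source pixels
#' @slot provenance list: source plane name, normalization, signed-plane
#'   affine shift, response description
#' @export
setClass("RGBImage",
  representation(rgb = "array", invalidMask = "matrix", provenance = "list"),
  validity = function(object) {
    msg <- NULL
    d <- dim(object@rgb)
    if (length(d) != 3L || d[3] != 3L) msg <- c(msg, "rgb must be r x c x 3")
    if (any(!is.finite(object@rgb))) msg <- c(msg, "non-finite rgb values")
    nrm <- object@provenance$norm
    if (!is.null(nrm) && !identical(nrm, "none")) {
      rng <- range(object@rgb)
      if (rng[1] < -1e-12 || rng[2] > 1 + 1e-12)
        msg <- c(msg, "normalized rgb outside [0, 1]")
    }
    if (is.null(msg)) TRUE else msg
  })

#' Mean ROI spectrum of one parameter
#'
#' Per-band arithmetic mean of one Stokes-related parameter over a binary
#' region of interest (one cell), with the ROI size and identity attached.
#'
#' @slot wavelengths band centers in nm
#' @slot values per-band ROI means (dimensionless for DOP/DOLP/DOCP,
#'   detector units for S0 unless normalized)
#' @slot nPixels ROI foreground pixel count
#' @slot parameter plane name the values came from
#' @slot cellId,classLabel cell identity
#' @export
setClass("Spectrum",
  representation(wavelengths = "numeric", values = "numeric",
                 nPixels = "integer", parameter = "character",
                 cellId = "character", classLabel = "character"),
  validity = function(object) {
    msg <- .checkWavelengths(object@wavelengths)
    if (length(object@values) != length(object@wavelengths))
      msg <- c(msg, "values length != band count")
    if (object@nPixels < 1L) msg <- c(msg, "nPixels must be >= 1")
    if (is.null(msg)) TRUE else msg
  })

#' Per-band two-sample test results
#'
#' Two-sided p-values per spectral band from a two-sample comparison of
#' per-cell mean spectra, with optional multiplicity-adjusted values kept
#' alongside (never replacing) the raw ones.
#'
#' @slot wavelengths band centers in nm
#' @slot pValues raw two-sided p-values in [0, 1]
#' @slot pAdjusted adjusted p-values (length 0 if no adjustment requested)
#' @slot adjustMethod adjustment method name ("none" or a
#'   \code{\link[stats]{p.adjust}} method)
#' @slot groupSizes integer c(nA, nB)
#' @slot parameter parameter the spectra were extracted from
#' @export
setClass("PValueSeries",
  representation(wavelengths = "numeric", pValues = "numeric",
                 pAdjusted = "numeric", adjustMethod = "character",
                 groupSizes = "integer", parameter = "character"),
  validity = function(object) {
    msg <- .checkWavelengths(object@wavelengths)
    if (length(object@pValues) != length(object@wavelengths))
      msg <- c(msg, "pValues length != band count")
    if (any(object@pValues < 0 | object@pValues > 1))
      msg <- c(msg, "p-values outside [0, 1]")
    if (length(object@pAdjusted) &&
        length(object@pAdjusted) != length(object@pValues))
      msg <- c(msg, "pAdjusted length mismatch")
    if (is.null(msg)) TRUE else msg
  })
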