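## Accessors and show() methods for the cube containers.

#' @rdname wavelengths
#' @export
setMethod("wavelengths", "AnalyzerStack", function(object) object@wavelengths)
#' @rdname wavelengths
#' @export
setMethod("wavelengths", "StokesCube", function(object) object@wavelengths)
#' @rdname wavelengths
#' @export
setMethod("wavelengths", "DerivedCube", function(object) object@wavelengths)
#' @rdname wavelengths
#' @export
setMethod("wavelengths", "SampleScene", function(object) object@wavelengths)
#' @rdname wavelengths
#' @export
setMethod("wavelengths", "SpectralResponse", function(object) object@wavelengths)
#' @rdname wavelengths
#' @export
setMethod("wavelengths", "Spectrum", function(object) object@wavelengths)
#' @rdname wavelengths
#' @export
setMethod("wavelengths", "PValueSeries", function(object) object@wavelengths)

#' @rdname nBands
#' @export
setMethod("nBands", "AnalyzerStack", function(object) dim(object@ih)[3])
#' @rdname nBands
#' @export
setMethod("nBands", "StokesCube", function(object) dim(object@s0)[3])
#' @rdname nBands
#' @export
setMethod("nBands", "DerivedCube", function(object) dim(object@dop)[3])
#' @rdname nBands
#' @export
setMethod("nBands", "SampleScene",
          function(object) dim(object@transmittance)[3])

#' @rdname spatialDims
#' @export
setMethod("spatialDims", "AnalyzerStack", function(object) dim(object@ih)[1:2])
#' @rdname spatialDims
#' @export
setMethod("spatialDims", "StokesCube", function(object) dim(object@s0)[1:2])
#' @rdname spatialDims
#' @export
setMethod("spatialDims", "DerivedCube", function(object) dim(object@dop)[1:2])
#' @rdname spatialDims
#' @export
setMethod("spatialDims", "SampleScene",
          function(object) dim(object@transmittance)[1:2])

.planeSlot <- function(object, plane, map) {
  key <- tolower(plane)
  if (!key %in% names(map))
    stop("unknown plane '", plane, "'; expected one of: ",
         paste(names(map), collapse = ", "), call. = FALSE)
  slot(object, map[[key]])
}

#' @rdname cubePlane
#' @export
setMethod("cubePlane", "AnalyzerStack", function(object, plane) {
  .planeSlot(object, plane,
             c(ih = "ih", iv = "iv", i45 = "i45", irc = "irc"))
})
#' @rdname cubePlane
#' @export
setMethod("cubePlane", "StokesCube", function(object, plane) {
  .planeSlot(object, plane, c(s0 = "s0", s1 = "s1", s2 = "s2", s3 = "s3"))
})
#' @rdname cubePlane
#' @export
setMethod("cubePlane", "DerivedCube", function(object, plane) {
  .planeSlot(object, plane, c(dop = "dop", dolp = "dolp", docp = "docp"))
})

#' Validity mask of a derived cube
#'
#' @param object a \linkS4class{DerivedCube}
#' @return logical array, TRUE where S0 exceeded the floor
#' @export
validMask <- function(object) {
  stopifnot(is(object, "DerivedCube"))
  object@maskValid
}

#' Number of values clipped into [0, 1]
#'
#' @param object a \linkS4class{DerivedCube}
#' @return integer count of clipped values (0 unless clip policy was "clip")
#' @export
clippedCount <- function(object) {
  stopifnot(is(object, "DerivedCube"))
  object@clippedCount
}

#' @rdname cellRecords
#' @export
setMethod("cellRecords", "SampleScene", function(object) object@cellRecords)

#' @rdname cellMask
#' @export
setMethod("cellMask", "SampleScene", function(object, cellId) {
  if (!cellId %in% object@cellRecords$cellId)
    stop("no cell with id ", cellId, " in this scene", call. = FALSE)
  object@cellMap == cellId
})

#' Per-pixel class label map of a scene
#'
#' @param scene a \linkS4class{SampleScene}
#' @return integer matrix of label codes (see \linkS4class{SampleScene})
#' @export
sceneLabels <- function(scene) {
  stopifnot(is(scene, "SampleScene"))
  scene@labels
}

#' Spectrum values accessor
#'
#' @param object a \linkS4class{Spectrum}
#' @return numeric vector of per-band means
#' @export
spectrumValues <- function(object) {
  stopifnot(is(object, "Spectrum"))
  object@values
}

#' Raw and adjusted p-values of a per-band test
#'
#' @param object a \linkS4class{PValueSeries}
#' @return data.frame with wavelength, p (raw) and, when computed,
#'   p_adj plus the adjustment method as an attribute
#' @export
pValues <- function(object) {
  stopifnot(is(object, "PValueSeries"))
  out <- data.frame(wavelength = object@wavelengths, p = object@pValues)
  if (length(object@pAdjusted)) out$p_adj <- object@pAdjusted
  attr(out, "adjustMethod") <- object@adjustMethod
  out
}

setMethod("show", "AnalyzerStack", function(object) {
  d <- dim(object@ih)
  cat(sprintf("AnalyzerStack: %d x %d pixels, %d band(s) [%g-%g nm]\n",
              d[1], d[2], d[3], min(object@wavelengths),
              max(object@wavelengths)))
  cat("  planes: Ih, Iv, I45, Irc\n")
})

setMethod("show", "StokesCube", function(object) {
  d <- dim(object@s0)
  cat(sprintf("StokesCube: %d x %d pixels, %d band(s) [%g-%g nm]\n",
              d[1], d[2], d[3], min(object@wavelengths),
              max(object@wavelengths)))
  cat(sprintf("  S0 range: [%.4g, %.4g]\n", min(object@s0), max(object@s0)))
})

setMethod("show", "DerivedCube", function(object) {
  d <- dim(object@dop)
  cat(sprintf("DerivedCube: %d x %d pixels, %d band(s)\n", d[1], d[2], d[3]))
  cat(sprintf("  valid pixels: %.1f%%; clipped values: %d\n",
              100 * mean(object@maskValid), object@clippedCount))
})

setMethod("show", "SampleScene", function(object) {
  d <- dim(object@transmittance)
  cr <- object@cellRecords
  cat(sprintf("SampleScene: %d x %d pixels, %d band(s) [%g-%g nm]\n",
              d[1], d[2], d[3], min(object@wavelengths),
              max(object@wavelengths)))
  if (nrow(cr)) {
    tab <- table(cr$class)
    cat("  cells:", paste(sprintf("%s=%d", names(tab), tab),
                          collapse = ", "), "\n")
  } else cat("  background-only scene\n")
})

setMethod("show", "Spectrum", function(object) {
  cat(sprintf("Spectrum of %s for cell %s (%s): %d bands, ROI %d px\n",
              object@parameter, object@cellId, object@classLabel,
              length(object@values), object@nPixels))
})

setMethod("show", "PValueSeries", function(object) {
  cat(sprintf(
    "PValueSeries (%s, n = %d vs %d): %d bands, %d with p < 0.05\n",
    object@parameter, object@groupSizes[1], object@groupSizes[2],
    length(object@pValues), sum(object@pValues < 0.05)))
})

setMethod("show", "PSAConfig", function(object) {
  cat(sprintf("PSAConfig '%s': LCVR1 %.4g rad, LCVR2 %.4g rad\n",
              object@label, object@retardance1, object@retardance2))
})

setMethod("show", "InstrumentGeometry", function(object) {
  cat(sprintf(
    "InstrumentGeometry: P1 %g deg, LCVR1 %g deg, LCVR2 %g deg, P2 %g deg\n",
    object@polarizer1Axis, object@lcvr1FastAxis, object@lcvr2FastAxis,
    object@polarizer2Axis))
})
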