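#' Band-center wavelengths of an object
#'
#' Accessor for the spectral axis (band centers, in nm) of cube-like
#' objects: \linkS4class{AnalyzerStack}, \linkS4class{StokesCube},
#' \linkS4class{DerivedCube}, \linkS4class{SampleScene},
#' \linkS4class{SpectralResponse} and \linkS4class{Spectrum}.
#'
#' @param object an object with a spectral axis
#' @return numeric vector of band centers in nm, strictly increasing
#' @export
setGeneric("wavelengths", function(object) standardGeneric("wavelengths"))

#' Number of spectral bands
#'
#' @param object a cube-like object
#' @return integer band count
#' @export
setGeneric("nBands", function(object) standardGeneric("nBands"))

#' Spatial dimensions (rows, columns)
#'
#' @param object a cube-like object
#' @return integer vector \code{c(rows, cols)}
#' @export
setGeneric("spatialDims", function(object) standardGeneric("spatialDims"))

#' Extract a named plane from a cube container
#'
#' For an \linkS4class{AnalyzerStack} the plane names are the analyzer
#' labels \code{"Ih"}, \code{"Iv"}, \code{"I45"}, \code{"Irc"}; for a
#' \linkS4class{StokesCube} they are \code{"S0"}..\code{"S3"}; for a
#' \linkS4class{DerivedCube} they are \code{"DOP"}, \code{"DOLP"},
#' \code{"DOCP"}.
#'
#' @param object the container
#' @param plane character plane name (case-insensitive)
#' @return numeric array \code{rows x cols x bands}
#' @export
setGeneric("cubePlane", function(object, plane) standardGeneric("cubePlane"))

#' Per-cell records of a synthetic scene
#'
#' @param object a \linkS4class{SampleScene}
#' @return data.frame with one row per placed cell (id, class, centroid,
#'   pixel count)
#' @export
setGeneric("cellRecords", function(object) standardGeneric("cellRecords"))

#' Binary mask of one cell in a scene
#'
#' @param object a \linkS4class{SampleScene}
#' @param cellId integer cell identifier (see \code{\link{cellRecords}})
#' @return logical matrix, TRUE over the cell's pixels
#' @export
setGeneric("cellMask", function(object, cellId) standardGeneric("cellMask"))
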