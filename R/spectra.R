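## ROI spectral signatures and per-band group comparison: mean spectra over
## binary cell masks, normalization, per-band two-sample t-tests (Welch by
## default) and spectral extrema localization.

#' Mean ROI spectrum of a cube plane
#'
#' Per band, the arithmetic mean of the plane over the mask's foreground
#' pixels; background pixels are excluded entirely, so spectra are invariant
#' to anything outside the ROI.
#'
#' @param plane numeric array rows x cols x bands
#' @param mask logical (or 0/1) matrix matching the spatial grid, at least
#'   one foreground pixel
#' @param wavelengths band centers in nm
#' @param parameter,cellId,classLabel identity attached to the spectrum
#' @return a \linkS4class{Spectrum}
#' @examples
#' pl <- array(0.7, c(8, 8, 3))
#' m <- matrix(FALSE, 8, 8); m[3:5, 3:5] <- TRUE
#' spectrumValues(extractMeanSpectrum(pl, m, c(500, 550, 600)))
#' @export
extractMeanSpectrum <- function(plane, mask, wavelengths,
                                parameter = "value", cellId = "roi",
                                classLabel = "unknown") {
  if (is.matrix(plane)) plane <- array(plane, c(dim(plane), 1L))
  stopifnot(length(dim(plane)) == 3L)
  mask <- mask > 0
  if (!identical(dim(mask), dim(plane)[1:2]))
    stop("mask shape (", paste(dim(mask), collapse = "x"),
         ") does not match the cube's spatial grid (",
         paste(dim(plane)[1:2], collapse = "x"), ")", call. = FALSE)
  n <- sum(mask)
  if (n == 0L) stop("empty ROI mask", call. = FALSE)
  vals <- vapply(seq_len(dim(plane)[3]),
                 function(b) mean(plane[, , b][mask]), numeric(1))
  new("Spectrum", wavelengths = as.numeric(wavelengths), values = vals,
      nPixels = as.integer(n), parameter = parameter,
      cellId = as.character(cellId), classLabel = classLabel)
}

#' Per-cell mean spectra of a simulated scene
#'
#' Applies every cell's ground-truth mask to the requested Stokes-related
#' planes and returns one tidy row per (cell, parameter, band).
#'
#' @param scene a \linkS4class{SampleScene} providing masks and classes
#' @param stokes a \linkS4class{StokesCube} on the scene's grid
#' @param derived a \linkS4class{DerivedCube} on the scene's grid
#' @param parameters plane names among S0, S1, S2, S3, DOP, DOLP, DOCP
#' @return data.frame: cellId, class, parameter, wavelength, value,
#'   nPixels
#' @export
extractCellSpectra <- function(scene, stokes, derived,
                               parameters = c("S0", "DOP", "DOLP",
                                              "DOCP")) {
  stopifnot(is(scene, "SampleScene"))
  planeOf <- function(p) {
    if (toupper(p) %in% c("S0", "S1", "S2", "S3")) cubePlane(stokes, p)
    else cubePlane(derived, p)
  }
  cr <- cellRecords(scene)
  out <- vector("list", nrow(cr) * length(parameters))
  k <- 0L
  for (p in parameters) {
    pl <- planeOf(p)
    for (i in seq_len(nrow(cr))) {
      sp <- extractMeanSpectrum(pl, cellMask(scene, cr$cellId[i]),
                                wavelengths(scene), parameter = toupper(p),
                                cellId = cr$cellId[i],
                                classLabel = cr$class[i])
      k <- k + 1L
      out[[k]] <- data.frame(cellId = cr$cellId[i], class = cr$class[i],
                             parameter = toupper(p),
                             wavelength = sp@wavelengths,
                             value = sp@values, nPixels = sp@nPixels)
    }
  }
  do.call(rbind, out)
}

#' Normalize a spectrum
#'
#' @param s a \linkS4class{Spectrum}
#' @param method \code{"max"} divides by the maximum value, \code{"area"}
#'   by the sum, \code{"none"} returns the input unchanged
#' @return a \linkS4class{Spectrum}
#' @examples
#' s <- new("Spectrum", wavelengths = c(1, 2, 3) + 500,
#'          values = c(2, 4, 8), nPixels = 1L, parameter = "S0",
#'          cellId = "c", classLabel = "x")
#' spectrumValues(normalizeSpectrum(s, "max"))    # 0.25 0.5 1
#' @export
normalizeSpectrum <- function(s, method = c("max", "area", "none")) {
  method <- match.arg(method)
  stopifnot(is(s, "Spectrum"))
  if (method == "none") return(s)
  denom <- switch(method, max = max(s@values), area = sum(s@values))
  if (!is.finite(denom) || denom == 0)
    stop("cannot ", method, "-normalize an all-zero spectrum",
         call. = FALSE)
  s@values <- s@values / denom
  s
}

## Spectra lists -> cells x bands matrix, checking one shared band grid.
.spectraMatrix <- function(group, wl = NULL) {
  if (is.matrix(group)) return(list(m = group, wl = wl))
  stopifnot(is.list(group), length(group) >= 1)
  wl0 <- wavelengths(group[[1]])
  m <- t(vapply(group, function(s) {
    stopifnot(is(s, "Spectrum"))
    if (!isTRUE(all.equal(wavelengths(s), wl0)))
      stop("spectra do not share one band grid", call. = FALSE)
    s@values
  }, numeric(length(wl0))))
  list(m = m, wl = wl0)
}

#' Per-band two-sample t-test between two groups of cell spectra
#'
#' For every spectral band, compares the per-cell mean values (one number
#' per cell per band — pixel-level pooling is deliberately not used) between
#' the two groups with a two-sided two-sample t-test, Welch's by default.
#' Raw p-values are always returned; Benjamini-Hochberg adjusted values are
#' computed alongside when requested, never replacing the raw series.
#'
#' @param groupA,groupB lists of \linkS4class{Spectrum} objects (or
#'   cells x bands numeric matrices) sharing one band grid; each group
#'   must contain at least 2 cells
#' @param varEqual use the pooled-variance Student's t instead of Welch
#' @param adjust \code{"BH"} (default) to also report Benjamini-Hochberg
#'   adjusted p-values, or \code{"none"}
#' @param wavelengths band grid, required only for matrix input
#' @param parameter parameter name carried into the result
#' @return a \linkS4class{PValueSeries}
#' @examples
#' a <- matrix(rnorm(10 * 3), 10)
#' b <- matrix(rnorm(12 * 3, mean = 2), 12)
#' pValues(perBandTTest(a, b, wavelengths = c(500, 550, 600)))
#' @export
perBandTTest <- function(groupA, groupB, varEqual = FALSE,
                         adjust = c("BH", "none"), wavelengths = NULL,
                         parameter = "value") {
  adjust <- match.arg(adjust)
  A <- .spectraMatrix(groupA, wavelengths)
  B <- .spectraMatrix(groupB, wavelengths)
  wl <- A$wl %||% B$wl %||% wavelengths
  if (is.null(wl)) stop("wavelengths required for matrix input",
                        call. = FALSE)
  if (ncol(A$m) != ncol(B$m))
    stop("groups have different band counts (", ncol(A$m), " vs ",
         ncol(B$m), ")", call. = FALSE)
  if (nrow(A$m) < 2 || nrow(B$m) < 2)
    stop("each group needs at least 2 cells", call. = FALSE)
  if (!is.null(A$wl) && !is.null(B$wl) &&
      !isTRUE(all.equal(A$wl, B$wl)))
    stop("the two groups are on different band grids", call. = FALSE)

  p <- vapply(seq_len(ncol(A$m)), function(b) {
    x <- A$m[, b]; y <- B$m[, b]
    if (stats::sd(x) < .Machine$double.eps^0.5 &&
        stats::sd(y) < .Machine$double.eps^0.5) {
      ## degenerate: both groups constant; equal means carry no evidence
      return(if (isTRUE(all.equal(mean(x), mean(y)))) 1 else 0)
    }
    stats::t.test(x, y, var.equal = varEqual,
                  alternative = "two.sided")$p.value
  }, numeric(1))

  padj <- if (adjust == "BH") stats::p.adjust(p, "BH") else numeric(0)
  new("PValueSeries", wavelengths = as.numeric(wl), pValues = p,
      pAdjusted = padj, adjustMethod = adjust,
      groupSizes = c(nrow(A$m), nrow(B$m)), parameter = parameter)
}

#' Locate interior spectral extrema
#'
#' Three-point comparison: band i is a peak when its value exceeds the left
#' neighbor and is at least the right neighbor (so a flat-topped plateau
#' reports its shortest-wavelength band), and symmetrically for troughs.
#' Endpoints are never reported. Results come back in wavelength order.
#'
#' @param s a \linkS4class{Spectrum} (or numeric vector with
#'   \code{wavelengths})
#' @param wavelengths band grid for vector input
#' @return data.frame: wavelength, value, kind ("peak"/"trough"); zero rows
#'   for monotone spectra
#' @examples
#' findSpectralExtrema(c(1, 3, 1), wavelengths = c(470, 480, 490))
#' @export
findSpectralExtrema <- function(s, wavelengths = NULL) {
  if (is(s, "Spectrum")) {
    v <- s@values; wl <- s@wavelengths
  } else {
    v <- as.numeric(s); wl <- as.numeric(wavelengths)
  }
  stopifnot(length(v) >= 3, length(wl) == length(v))
  n <- length(v)
  i <- 2:(n - 1)
  isPeak <- v[i] > v[i - 1] & v[i] >= v[i + 1]
  isTrough <- v[i] < v[i - 1] & v[i] <= v[i + 1]
  idx <- i[isPeak | isTrough]
  kind <- ifelse(isPeak[match(idx, i)], "peak", "trough")
  data.frame(wavelength = wl[idx], value = v[idx], kind = kind)[
    order(wl[idx]), , drop = FALSE]
}
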