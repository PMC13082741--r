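## Cube and image serialization. Two cube formats:
##   * ENVI-style: text header (<path>.hdr) + raw band-sequential float64,
##     little-endian — the bit-exact primary format;
##   * multi-page TIFF: float32 pages scaled into [0, 1], with the affine
##     scale recorded in the sidecar, exact to float32 precision.
## Both carry a JSON sidecar (<path>.json) with wavelengths, plane order and
## provenance; bands are returned in increasing wavelength order regardless
## of on-disk order.

.sidecarPath <- function(path) paste0(path, ".json")

.writeSidecar <- function(path, wavelengths, extra = list()) {
  meta <- c(list(format_version = 1L,
                 wavelengths = as.numeric(wavelengths),
                 band_order = seq_along(wavelengths),
                 written = "PolStokes"), extra)
  jsonlite::write_json(meta, .sidecarPath(path), auto_unbox = TRUE,
                       digits = NA)
}

#' Write a data cube to disk
#'
#' @param x numeric array rows x cols x bands
#' @param path output path (the ENVI writer adds \code{<path>.hdr}; both
#'   writers add a \code{<path>.json} sidecar)
#' @param wavelengths band centers in nm, one per band
#' @param format \code{"envi"} (float64 raw + text header; bit-exact) or
#'   \code{"tiff"} (multi-page float32, values affinely scaled into [0, 1]
#'   with the scale recorded in the sidecar)
#' @param metadata extra provenance stored in the sidecar
#' @return the path, invisibly
#' @export
writeCube <- function(x, path, wavelengths, format = c("envi", "tiff"),
                      metadata = list()) {
  format <- match.arg(format)
  if (is.matrix(x)) x <- array(x, c(dim(x), 1L))
  stopifnot(length(dim(x)) == 3L, dim(x)[3] == length(wavelengths))
  d <- dim(x)
  if (format == "envi") {
    hdr <- c("ENVI",
             sprintf("samples = %d", d[2]),
             sprintf("lines = %d", d[1]),
             sprintf("bands = %d", d[3]),
             "header offset = 0",
             "file type = ENVI Standard",
             "data type = 5",
             "interleave = bsq",
             "byte order = 0",
             paste0("wavelength = { ",
                    paste(format(wavelengths, trim = TRUE),
                          collapse = " , "), " }"))
    writeLines(hdr, paste0(path, ".hdr"))
    con <- file(path, "wb")
    on.exit(close(con))
    ## BSQ: band-major, rows within a band written in row-major order
    for (b in seq_len(d[3]))
      writeBin(as.vector(t(x[, , b])), con, size = 8, endian = "little")
    .writeSidecar(path, wavelengths,
                  c(list(format = "envi"), metadata))
  } else {
    lo <- min(x); hi <- max(x)
    span <- if (hi > lo) hi - lo else 1
    pages <- lapply(seq_len(d[3]),
                    function(b) (x[, , b] - lo) / span)
    tiff::writeTIFF(pages, path, bits.per.sample = 32L)
    .writeSidecar(path, wavelengths,
                  c(list(format = "tiff",
                         scale = list(offset = lo, span = span)),
                    metadata))
  }
  invisible(path)
}

#' Read a data cube from disk
#'
#' Reads ENVI (header + raw) or multi-page TIFF cubes written by
#' \code{\link{writeCube}}, validating header/page-count consistency and
#' returning bands ordered by increasing wavelength regardless of on-disk
#' order.
#'
#' @param path the path given to \code{\link{writeCube}}
#' @return list with \code{data} (rows x cols x bands array),
#'   \code{wavelengths} and \code{metadata}
#' @export
readCube <- function(path) {
  sc <- .sidecarPath(path)
  if (!file.exists(sc))
    stop("missing sidecar '", sc, "'; cubes must be read from a path ",
         "written by writeCube() (raster + JSON sidecar)", call. = FALSE)
  meta <- jsonlite::read_json(sc, simplifyVector = TRUE)
  wl <- as.numeric(meta$wavelengths)
  if (identical(meta$format, "envi")) {
    hdrPath <- paste0(path, ".hdr")
    if (!file.exists(hdrPath))
      stop("missing ENVI header '", hdrPath, "'", call. = FALSE)
    hdr <- readLines(hdrPath)
    gethdr <- function(key) {
      ln <- grep(paste0("^", key, " *="), hdr, value = TRUE)[1]
      as.integer(sub(".*= *", "", ln))
    }
    nsamp <- gethdr("samples"); nline <- gethdr("lines")
    nband <- gethdr("bands")
    if (length(wl) != nband)
      stop("sidecar lists ", length(wl), " wavelengths but the ENVI ",
           "header declares ", nband, " bands", call. = FALSE)
    nExpect <- nsamp * nline * nband
    raw <- readBin(path, "double", n = nExpect + 1L, size = 8,
                   endian = "little")
    if (length(raw) != nExpect)
      stop("ENVI payload has ", length(raw), " values, header implies ",
           nExpect, call. = FALSE)
    x <- array(0, c(nline, nsamp, nband))
    for (b in seq_len(nband)) {
      off <- (b - 1L) * nsamp * nline
      x[, , b] <- matrix(raw[off + seq_len(nsamp * nline)], nline, nsamp,
                         byrow = TRUE)
    }
  } else if (identical(meta$format, "tiff")) {
    pages <- tiff::readTIFF(path, all = TRUE)
    if (!is.list(pages)) pages <- list(pages)
    if (length(pages) != length(wl))
      stop("sidecar lists ", length(wl), " wavelengths but the TIFF has ",
           length(pages), " pages", call. = FALSE)
    sc <- meta$scale
    x <- array(0, c(dim(pages[[1]]), length(pages)))
    for (b in seq_along(pages))
      x[, , b] <- pages[[b]] * sc$span + sc$offset
  } else {
    stop("unknown cube format '", meta$format, "' in sidecar",
         call. = FALSE)
  }
  ord <- order(wl)
  list(data = x[, , ord, drop = FALSE], wavelengths = wl[ord],
       metadata = meta)
}

#' Write an analyzer stack as four cubes
#'
#' One cube per analyzer, named \code{Ih}, \code{Iv}, \code{I45},
#' \code{Irc} under \code{dir}.
#'
#' @param stack an \linkS4class{AnalyzerStack}
#' @param dir output directory (created if needed)
#' @param format cube format, see \code{\link{writeCube}}
#' @return named character vector of the four paths
#' @export
writeAnalyzerStack <- function(stack, dir, format = "envi") {
  stopifnot(is(stack, "AnalyzerStack"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  ext <- if (format == "tiff") ".tif" else ".raw"
  paths <- c(Ih = "ih", Iv = "iv", I45 = "i45", Irc = "irc")
  out <- vapply(names(paths), function(lbl) {
    p <- file.path(dir, paste0(paths[[lbl]], ext))
    writeCube(cubePlane(stack, lbl), p, wavelengths(stack),
              format = format, metadata = list(analyzer = lbl))
    p
  }, character(1))
  out
}

#' Read an analyzer stack from a directory of four cubes
#'
#' @param dir directory holding cubes named ih/iv/i45/irc (any shared
#'   extension) as written by \code{\link{writeAnalyzerStack}}
#' @return an \linkS4class{AnalyzerStack}
#' @export
readAnalyzerStack <- function(dir) {
  pick <- function(stem) {
    hits <- list.files(dir, pattern = paste0("^", stem, "\\.(raw|tif)$"),
                       full.names = TRUE)
    if (length(hits) != 1L)
      stop("expected exactly one '", stem, ".raw' or '", stem,
           ".tif' in ", dir, call. = FALSE)
    readCube(hits)
  }
  ih <- pick("ih"); iv <- pick("iv"); i45 <- pick("i45"); irc <- pick("irc")
  analyzerStack(ih$data, iv$data, i45$data, irc$data, ih$wavelengths,
                metadata = list(source = dir))
}

#' Write a binary ROI/label mask as PNG
#'
#' Foreground is written as 255, background as 0; an integer label map is
#' scaled into 8 bits and its legend written as \code{<path>.json}.
#'
#' @param mask logical or small-integer matrix
#' @param path output PNG path
#' @param legend named list mapping label names to codes (for label maps)
#' @return the path, invisibly
#' @export
writeMask <- function(mask, path, legend = NULL) {
  if (is.logical(mask)) {
    png::writePNG(mask * 1.0, path)
  } else {
    mx <- max(mask, 1L)
    png::writePNG(mask / mx, path)
    legend <- c(legend %||% list(), list(maxCode = mx))
  }
  if (!is.null(legend))
    jsonlite::write_json(legend, paste0(path, ".json"), auto_unbox = TRUE)
  invisible(path)
}

#' Read a binary ROI mask from PNG
#'
#' @param path PNG path (0 = background, anything above half scale =
#'   foreground)
#' @return logical matrix
#' @export
readMask <- function(path) {
  x <- png::readPNG(path)
  if (length(dim(x)) == 3L) x <- x[, , 1]
  x > 0.5
}

#' Write tidy spectra to CSV
#'
#' Column layout: cellId, class, parameter, wavelength, value, nPixels.
#' Numbers are printed with full precision so reruns are byte-comparable.
#'
#' @param spectra data.frame from \code{\link{extractCellSpectra}}
#' @param path output CSV path
#' @return the path, invisibly
#' @export
writeSpectraCSV <- function(spectra, path) {
  df <- spectra
  for (nm in names(df))
    if (is.numeric(df[[nm]]))
      df[[nm]] <- formatC(df[[nm]], digits = 17, format = "g")
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Write per-band p-values to CSV
#'
#' @param series a \linkS4class{PValueSeries} or a list of them
#' @param path output CSV path
#' @return the path, invisibly
#' @export
writePValuesCSV <- function(series, path) {
  if (is(series, "PValueSeries")) series <- list(series)
  rows <- lapply(series, function(s) {
    df <- data.frame(parameter = s@parameter, wavelength = s@wavelengths,
                     p_raw = s@pValues)
    df$p_bh <- if (length(s@pAdjusted)) s@pAdjusted else NA_real_
    df
  })
  df <- do.call(rbind, rows)
  for (nm in c("wavelength", "p_raw", "p_bh"))
    df[[nm]] <- formatC(df[[nm]], digits = 17, format = "g")
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}
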