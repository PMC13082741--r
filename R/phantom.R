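## Synthetic blood-smear phantom: the software stand-in for a stained smear
## under the microscope. Each cell is an ellipse carrying a per-pixel optical
## model: transmittance from a Beer-Lambert stain curve scaled by local
## chromatin density, an isotropic depolarization factor with class-specific
## texture, and a weak linear retardance.

.WBC_CLASSES <- c("granulocyte", "lymphocyte", "monocyte")
.LABEL_CODES <- c(background = 0L, granulocyte = 1L, lymphocyte = 2L,
                  monocyte = 3L, nucleus = 4L, granule = 5L)

#' Default simulation band grid
#'
#' 29 bands from 470 to 750 nm at 10 nm spacing, the visible range the
#' instrument's spectral analysis covers.
#'
#' @return numeric vector of band centers in nm
#' @export
defaultWavelengths <- function() seq(470, 750, by = 10)

#' Construct a phantom specification
#'
#' Defaults describe the standard simulated study field: granulocyte-like
#' cells with granular depolarizing cytoplasm (mean depolarization factor
#' 0.5), lymphocyte-like cells with a smooth low-amplitude surface texture
#' (mean 0.3), monocyte-like cells with a large lobed nucleus (mean 0.4),
#' between-cell SD 0.05, a Wright-stain-like transmission minimum near
#' 535 nm, and 1\% Gaussian measurement noise.
#'
#' @param imageSize scalar or c(rows, cols) image size in pixels
#' @param nCellsPerClass named counts for granulocyte/lymphocyte/monocyte
#'   (unnamed scalar = same count per class)
#' @param cellRadiusRange c(min, max) cell semi-axis range in pixels
#' @param granuleDensity fraction of granulocyte pixels with a granule
#' @param granuleDepolContrast granule depolarization texture amplitude
#' @param surfaceTextureAmplitude lymphocyte surface texture amplitude
#' @param nucleusLobedness monocyte nucleus lobedness in [0, 1]
#' @param classDepolMean named per-class mean depolarization factor
#' @param classDepolSD between-cell SD of the depolarization factor
#' @param depolDispersion fractional decrease of depolarization from the
#'   blue to the red end of the grid
#' @param stainTransmission list(baseline, depth, center, width) of the
#'   stain's Gaussian absorption band (nm)
#' @param stainUptakeSD between-cell SD of the multiplicative stain uptake
#'   factor (cell-to-cell staining variability)
#' @param wavelengths band grid in nm
#' @param noiseModel list(type, sd | scale); \code{sd} is the Gaussian sigma
#'   as a fraction of full scale
#' @param seed integer seed; fully determines the phantom
#' @param maxPlaceAttempts placement attempts per cell before failing
#' @return a \linkS4class{PhantomSpec}
#' @examples
#' phantomSpec(imageSize = 96, nCellsPerClass = 2, seed = 1)
#' @export
phantomSpec <- function(imageSize = 192,
                        nCellsPerClass = c(granulocyte = 5L,
                                           lymphocyte = 5L, monocyte = 2L),
                        cellRadiusRange = c(7, 12),
                        granuleDensity = 0.3,
                        granuleDepolContrast = 0.3,
                        surfaceTextureAmplitude = 0.05,
                        nucleusLobedness = 0.6,
                        classDepolMean = c(granulocyte = 0.5,
                                           lymphocyte = 0.3,
                                           monocyte = 0.4),
                        classDepolSD = 0.05,
                        depolDispersion = 0.15,
                        stainTransmission = list(baseline = 0.92,
                                                 depth = 0.45,
                                                 center = 535, width = 30),
                        stainUptakeSD = 0.1,
                        wavelengths = defaultWavelengths(),
                        noiseModel = list(type = "gaussian", sd = 0.01),
                        seed = 1L,
                        maxPlaceAttempts = 200L) {
  if (length(imageSize) == 1L) imageSize <- c(imageSize, imageSize)
  if (is.null(names(nCellsPerClass))) {
    nCellsPerClass <- rep(as.integer(nCellsPerClass), length.out = 3L)
    names(nCellsPerClass) <- .WBC_CLASSES
  }
  full <- stats::setNames(integer(3), .WBC_CLASSES)
  full[names(nCellsPerClass)] <- as.integer(nCellsPerClass)
  means <- stats::setNames(rep(NA_real_, 3), .WBC_CLASSES)
  means[names(classDepolMean)] <- classDepolMean
  if (anyNA(means)) stop("classDepolMean must cover all three classes")
  new("PhantomSpec",
      imageSize = as.integer(imageSize), nCellsPerClass = full,
      cellRadiusRange = as.numeric(cellRadiusRange),
      granuleDensity = granuleDensity,
      granuleDepolContrast = granuleDepolContrast,
      surfaceTextureAmplitude = surfaceTextureAmplitude,
      nucleusLobedness = nucleusLobedness,
      classDepolMean = means, classDepolSD = classDepolSD,
      depolDispersion = depolDispersion,
      stainTransmission = stainTransmission,
      stainUptakeSD = stainUptakeSD,
      wavelengths = as.numeric(wavelengths), noiseModel = noiseModel,
      seed = as.integer(seed),
      maxPlaceAttempts = as.integer(maxPlaceAttempts))
}

## Evaluate the stain transmission curve on a wavelength grid.
stainTransmissionCurve <- function(st, wavelengths) {
  pmax(0, pmin(1, st$baseline -
                 st$depth * exp(-0.5 * ((wavelengths - st$center) /
                                          st$width)^2)))
}

## Run expr with a private RNG stream; the caller's RNG state is untouched.
withSeed <- function(seed, expr) {
  has <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (has) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(as.integer(seed %% .Machine$integer.max))
  expr
}

## Elliptical mask: TRUE inside an ellipse with semi-axes (ra, rb) rotated by
## theta radians, centered at (cr, cc); coordinates are (row, col), 1-based.
.ellipseMask <- function(nr, nc, cr, cc, ra, rb, theta) {
  rows <- matrix(seq_len(nr), nr, nc)
  cols <- matrix(seq_len(nc), nr, nc, byrow = TRUE)
  dy <- rows - cr; dx <- cols - cc
  u <- cos(theta) * dx + sin(theta) * dy
  v <- -sin(theta) * dx + cos(theta) * dy
  (u / ra)^2 + (v / rb)^2 <= 1
}

## Two-pass separable box blur with edge replication; small-kernel smoother
## for the lymphocyte surface texture.
.boxBlur <- function(m, radius = 2L, passes = 2L) {
  k <- 2L * radius + 1L
  blur1d <- function(x) {
    n <- length(x)
    xp <- c(rep(x[1], radius), x, rep(x[n], radius))
    cs <- cumsum(xp)
    (cs[(k):(n + k - 1L)] - c(0, cs[seq_len(n - 1L)])) / k
  }
  for (p in seq_len(passes)) {
    m <- apply(m, 2L, blur1d)
    m <- t(apply(m, 1L, blur1d))
  }
  m
}

.clip01 <- function(x) pmax(0, pmin(1, x))

#' Generate a synthetic blood-smear scene
#'
#' Places non-overlapping elliptical cells of the three white-blood-cell
#' classes on a clear background and renders the per-pixel optical model:
#' \itemize{
#'   \item granulocytes: high-spatial-frequency granule speckle added to the
#'     cell's depolarization factor (zero-mean, amplitude
#'     \code{granuleDepolContrast}); granule pixels absorb slightly more;
#'   \item lymphocytes: smooth low-amplitude surface texture in both
#'     depolarization and retardance;
#'   \item monocytes: a large lobed nucleus (union of offset ellipses, the
#'     offset set by \code{nucleusLobedness}) with higher chromatin density,
#'     hence stronger absorption, and a small depolarization bump.
#' }
#' Transmittance follows Beer-Lambert: t = exp(-density * A(lambda)) with
#' A(lambda) from the stain transmission curve, so every pixel shares the
#' stain's spectral shape scaled by local chromatin density. The
#' depolarization factor decreases linearly with wavelength by
#' \code{depolDispersion} across the grid. The output is fully determined by
#' the spec's seed.
#'
#' @param spec a \linkS4class{PhantomSpec}
#' @return a \linkS4class{SampleScene}
#' @examples
#' scene <- generatePhantom(phantomSpec(imageSize = 96,
#'                                      nCellsPerClass = 1, seed = 7))
#' cellRecords(scene)
#' @export
generatePhantom <- function(spec) {
  stopifnot(is(spec, "PhantomSpec"))
  validObject(spec)
  withSeed(spec@seed, .generatePhantomImpl(spec))
}

.generatePhantomImpl <- function(spec) {
  nr <- spec@imageSize[1]; nc <- spec@imageSize[2]
  wl <- spec@wavelengths; nb <- length(wl)

  labels <- matrix(.LABEL_CODES[["background"]], nr, nc)
  cellMap <- matrix(0L, nr, nc)
  density <- matrix(0.05, nr, nc)        # faint background stain residue
  dBase <- matrix(0, nr, nc)             # depolarization factor, band-free
  retard <- matrix(0, nr, nc)
  retAxis <- matrix(0, nr, nc)

  recs <- list()
  cellId <- 0L
  classes <- rep(.WBC_CLASSES, times = spec@nCellsPerClass[.WBC_CLASSES])

  for (cls in classes) {
    cellId <- cellId + 1L
    ## monocytes are the large class: bias their size to the top of range
    rr <- spec@cellRadiusRange
    if (cls == "monocyte") rr <- c(mean(rr), rr[2] * 1.2)
    placed <- FALSE
    for (att in seq_len(spec@maxPlaceAttempts)) {
      ra <- stats::runif(1, rr[1], rr[2])
      rb <- stats::runif(1, rr[1], rr[2])
      th <- stats::runif(1, 0, pi)
      rmax <- max(ra, rb) + 1
      if (nr - 2 * rmax < 1 || nc - 2 * rmax < 1) next
      cr <- stats::runif(1, rmax + 1, nr - rmax)
      cc <- stats::runif(1, rmax + 1, nc - rmax)
      m <- .ellipseMask(nr, nc, cr, cc, ra, rb, th)
      if (!any(m)) next
      ## require a 1-px margin to already-placed cells
      grown <- .ellipseMask(nr, nc, cr, cc, ra + 1, rb + 1, th)
      if (any(cellMap[grown] > 0)) next
      placed <- TRUE
      break
    }
    if (!placed)
      stop("could not place cell ", cellId, " (", cls, ") without overlap ",
           "after ", spec@maxPlaceAttempts, " attempts; reduce cell count ",
           "or size, or enlarge the image", call. = FALSE)

    cellMap[m] <- cellId
    labels[m] <- .LABEL_CODES[[cls]]
    density[m] <- 1

    dCell <- .clip01(stats::rnorm(1, spec@classDepolMean[[cls]],
                                  spec@classDepolSD))
    dField <- matrix(0, nr, nc)
    dField[m] <- dCell
    retard[m] <- stats::runif(1, 0.1, 0.4)
    retAxis[m] <- stats::runif(1, 0, 180)

    if (cls == "granulocyte" && spec@granuleDepolContrast > 0) {
      g <- m & (matrix(stats::runif(nr * nc), nr, nc) < spec@granuleDensity)
      ## zero-mean speckle: granules up, inter-granule cytoplasm down
      tex <- spec@granuleDepolContrast *
        ((g) - spec@granuleDensity) * 1.0
      dField[m] <- dField[m] + tex[m]
      labels[g] <- .LABEL_CODES[["granule"]]
      density[g] <- 1.3
    } else if (cls == "lymphocyte" && spec@surfaceTextureAmplitude > 0) {
      noise <- .boxBlur(matrix(stats::rnorm(nr * nc), nr, nc), 2L, 2L)
      noise <- noise / max(stats::sd(noise[m]), 1e-12)
      noise <- noise - mean(noise[m])
      dField[m] <- dField[m] + spec@surfaceTextureAmplitude * noise[m]
      retard[m] <- .clip01(retard[m] +
                             0.5 * spec@surfaceTextureAmplitude * noise[m])
      ## lymphocytes are small dense-nucleus cells: most of the area is
      ## nucleus; mark an inner core
      core <- .ellipseMask(nr, nc, cr, cc, 0.7 * ra, 0.7 * rb, th)
      labels[core & m] <- .LABEL_CODES[["nucleus"]]
      density[core & m] <- 1.5
    } else if (cls == "monocyte") {
      ## lobed nucleus: two offset ellipses whose separation grows with
      ## lobedness
      off <- spec@nucleusLobedness * 0.45 * max(ra, rb)
      n1 <- .ellipseMask(nr, nc, cr - off * sin(th), cc + off * cos(th),
                         0.5 * ra, 0.55 * rb, th)
      n2 <- .ellipseMask(nr, nc, cr + off * sin(th), cc - off * cos(th),
                         0.55 * ra, 0.5 * rb, th + 0.3)
      nuc <- (n1 | n2) & m
      labels[nuc] <- .LABEL_CODES[["nucleus"]]
      density[nuc] <- 1.8
      dField[nuc] <- dField[nuc] + 0.05
    }

    dField[m] <- .clip01(dField[m])
    dBase[m] <- dField[m]

    ## cell-to-cell staining variability: multiplicative uptake factor
    if (spec@stainUptakeSD > 0)
      density[m] <- density[m] *
        max(0.2, stats::rnorm(1, 1, spec@stainUptakeSD))

    px <- which(m, arr.ind = TRUE)
    recs[[cellId]] <- data.frame(
      cellId = cellId, class = cls,
      centroidRow = mean(px[, 1]), centroidCol = mean(px[, 2]),
      nPixels = nrow(px), depolMean = mean(dField[m]))
  }

  ## spectral expansion
  tCurve <- stainTransmissionCurve(spec@stainTransmission, wl)
  absorb <- -log(pmax(tCurve, 1e-6))
  trans <- array(0, c(nr, nc, nb))
  depol <- array(0, c(nr, nc, nb))
  span <- max(wl) - min(wl)
  mid <- (max(wl) + min(wl)) / 2
  for (b in seq_len(nb)) {
    trans[, , b] <- exp(-density * absorb[b])
    fac <- 1 + spec@depolDispersion * (mid - wl[b]) / max(span, 1)
    depol[, , b] <- .clip01(dBase * fac)
  }

  cr <- if (length(recs)) do.call(rbind, recs) else
    data.frame(cellId = integer(), class = character(),
               centroidRow = numeric(), centroidCol = numeric(),
               nPixels = integer(), depolMean = numeric())

  new("SampleScene", wavelengths = wl, transmittance = trans, depol = depol,
      retardance = retard, retAxis = retAxis, labels = labels,
      cellMap = cellMap, cellRecords = cr,
      metadata = list(spec = spec, labelCodes = .LABEL_CODES))
}

#' Sample Mueller matrix of one scene pixel
#'
#' Materializes the 4x4 Mueller matrix encoded parametrically in a scene:
#' transmittance x linear retarder x isotropic partial depolarizer.
#'
#' @param scene a \linkS4class{SampleScene}
#' @param row,col pixel coordinates (1-based)
#' @param band spectral band index
#' @return 4x4 Mueller matrix
#' @export
sceneMueller <- function(scene, row, col, band) {
  stopifnot(is(scene, "SampleScene"))
  d <- dim(scene@transmittance)
  stopifnot(row >= 1, row <= d[1], col >= 1, col <= d[2],
            band >= 1, band <= d[3])
  scene@transmittance[row, col, band] *
    variableRetarder(scene@retAxis[row, col], scene@retardance[row, col]) %*%
    partialDepolarizer(scene@depol[row, col, band])
}
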