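## End-to-end orchestration: simulate -> reconstruct -> derive -> render ->
## extract -> test, with every intermediate written to disk and a manifest
## tying outputs to the config hash and seed.

.logMsg <- function(level, config, ...) {
  levels <- c(quiet = 0, info = 1, debug = 2)
  if (levels[[config@logLevel]] >= levels[[level]])
    message("[", level, "] ", ...)
}

#' Run the full simulated-acquisition pipeline
#'
#' Stages, in order: phantom generation, four-analyzer acquisition
#' simulation, Stokes reconstruction, DOP/DOLP/DOCP derivation, synthetic
#' RGB rendering of S0..S3 and the three derived planes, ground-truth-mask
#' spectrum extraction for S0/DOP/DOLP/DOCP, and per-band Welch t-tests
#' between every pair of cell classes present (granulocyte vs lymphocyte
#' first) for S0, DOP and DOLP. Each stage's outputs are written under the
#' config's output directory; the manifest records the config hash and the
#' seeds, so rerunning the same config reproduces identical numeric output.
#'
#' The phantom seed and the acquisition noise seed are derived
#' deterministically from the config's master seed.
#'
#' @param config a \linkS4class{RunConfig}
#' @return (invisibly) a list: \code{manifest} (also written as
#'   \code{manifest.json}), plus the in-memory \code{scene}, \code{stack},
#'   \code{stokes}, \code{derived}, \code{spectra} and \code{tests}
#' @examples
#' \donttest{
#' cfg <- runConfig(phantom = phantomSpec(imageSize = 96,
#'                                        nCellsPerClass = 2, seed = 5),
#'                  outDir = tempfile(), logLevel = "quiet")
#' res <- runPipeline(cfg)
#' res$manifest$files$pvalues
#' }
#' @export
runPipeline <- function(config) {
  stopifnot(is(config, "RunConfig"))
  validObject(config)
  out <- config@outDir
  dir.create(out, recursive = TRUE, showWarnings = FALSE)
  hash <- configHash(config)
  fmt <- config@cubeFormat
  ext <- if (fmt == "tiff") ".tif" else ".raw"

  stage <- function(name, expr) {
    .logMsg("info", config, "stage ", name)
    tryCatch(expr, error = function(e)
      stop("pipeline stage '", name, "' failed: ", conditionMessage(e),
           call. = FALSE))
  }

  ## seeds derived from the master seed; kept below 2^31
  phSeed <- (config@seed * 1000L + 1L) %% 2147483647L
  acqSeed <- (config@seed * 1000L + 2L) %% 2147483647L

  ph <- config@phantom
  ph@seed <- as.integer(phSeed)
  scene <- stage("simulate/phantom", generatePhantom(ph))
  stack <- stage("simulate/acquire",
                 simulateAcquisition(scene, config@geometry,
                                     noiseModel = ph@noiseModel,
                                     seed = acqSeed))
  files <- list()
  files$analyzers <- stage("write/analyzers",
                           writeAnalyzerStack(stack, file.path(out, "raw"),
                                              format = fmt))
  files$labels <- stage("write/labels", {
    p <- file.path(out, "labels.png")
    writeMask(sceneLabels(scene), p,
              legend = as.list(scene@metadata$labelCodes))
    p
  })

  stokes <- stage("stokes", computeStokes(stack))
  files$stokes <- vapply(c("S0", "S1", "S2", "S3"), function(pl) {
    p <- file.path(out, paste0(tolower(pl), ext))
    writeCube(cubePlane(stokes, pl), p, wavelengths(stokes), format = fmt,
              metadata = list(plane = pl, configHash = hash))
    p
  }, character(1))

  derived <- stage("derive",
                   computeDerived(stokes, s0Floor = config@s0Floor,
                                  clipPolicy = config@clipPolicy))
  files$derived <- vapply(c("DOP", "DOLP", "DOCP"), function(pl) {
    p <- file.path(out, paste0(tolower(pl), ext))
    writeCube(cubePlane(derived, pl), p, wavelengths(derived),
              format = fmt, metadata = list(plane = pl, configHash = hash))
    p
  }, character(1))

  resp <- buildDefaultResponse(wavelengths(scene))
  renderPlanes <- c("S0", "S1", "S2", "S3", "DOP", "DOLP", "DOCP")
  files$rgb <- stage("rgb", vapply(renderPlanes, function(pl) {
    src <- if (pl %in% c("S0", "S1", "S2", "S3")) cubePlane(stokes, pl)
           else cubePlane(derived, pl)
    img <- hsiToRGB(src, resp, norm = config@rgbNorm,
                    p = config@rgbPercentile, planeName = pl)
    p <- file.path(out, paste0("rgb_", tolower(pl), ".png"))
    writeRGBImage(img, p)
    p
  }, character(1)))

  spectra <- stage("extract",
                   extractCellSpectra(scene, stokes, derived,
                                      parameters = c("S0", "DOP", "DOLP",
                                                     "DOCP")))
  files$spectra <- file.path(out, "spectra.csv")
  writeSpectraCSV(spectra, files$spectra)

  tests <- stage("ttest", {
    present <- unique(cellRecords(scene)$class)
    counts <- table(factor(cellRecords(scene)$class, levels = present))
    pairs <- utils::combn(present[counts[present] >= 2], 2,
                          simplify = FALSE)
    ## canonical first pair: granulocyte vs lymphocyte when both exist
    res <- list()
    for (pr in pairs) for (param in c("S0", "DOP", "DOLP")) {
      grab <- function(cls) {
        sub <- spectra[spectra$class == cls & spectra$parameter == param, ]
        ids <- unique(sub$cellId)
        t(vapply(ids, function(id)
          sub$value[sub$cellId == id], numeric(nBands(scene))))
      }
      ps <- perBandTTest(grab(pr[1]), grab(pr[2]),
                         wavelengths = wavelengths(scene),
                         parameter = param)
      res[[paste(param, pr[1], pr[2], sep = "_")]] <- ps
    }
    res
  })
  files$pvalues <- file.path(out, "pvalues.csv")
  if (length(tests)) writePValuesCSV(tests, files$pvalues)

  manifest <- list(configHash = hash, seed = config@seed,
                   phantomSeed = phSeed, acquisitionSeed = acqSeed,
                   package = as.character(utils::packageVersion("PolStokes")),
                   files = files,
                   clippedCount = clippedCount(derived),
                   nCells = nrow(cellRecords(scene)))
  jsonlite::write_json(manifest, file.path(out, "manifest.json"),
                       auto_unbox = TRUE, digits = NA)
  writeRunConfig(config, file.path(out, "config.yaml"))

  invisible(list(manifest = manifest, scene = scene, stack = stack,
                 stokes = stokes, derived = derived, spectra = spectra,
                 tests = tests))
}
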