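## Run configuration: one object holding every tunable of the end-to-end
## pipeline, round-trippable through a single YAML file with a versioned,
## fail-fast schema (unknown keys are rejected, not ignored).

.CONFIG_VERSION <- 1L

#' Pipeline run configuration
#'
#' @slot phantom the \linkS4class{PhantomSpec} defining the synthetic scene
#' @slot geometry the \linkS4class{InstrumentGeometry}
#' @slot s0Floor "auto" or a numeric S0 validity floor
#' @slot clipPolicy "clip", "flag" or "allow"
#' @slot rgbNorm display normalization for renderings
#' @slot rgbPercentile percentile for percentile normalization
#' @slot cubeFormat "envi" or "tiff"
#' @slot outDir output directory
#' @slot seed master seed of the run
#' @slot logLevel "quiet", "info" or "debug"
#' @export
setClass("RunConfig",
  representation(phantom = "PhantomSpec", geometry = "InstrumentGeometry",
                 s0Floor = "ANY", clipPolicy = "character",
                 rgbNorm = "character", rgbPercentile = "numeric",
                 cubeFormat = "character", outDir = "character",
                 seed = "integer", logLevel = "character"),
  validity = function(object) {
    msg <- NULL
    if (!(identical(object@s0Floor, "auto") ||
          (is.numeric(object@s0Floor) && object@s0Floor >= 0)))
      msg <- c(msg, "s0Floor must be \"auto\" or a nonnegative number")
    if (!object@clipPolicy %in% c("clip", "flag", "allow"))
      msg <- c(msg, "bad clipPolicy")
    if (!object@rgbNorm %in% c("percentile", "per_channel", "global"))
      msg <- c(msg, "bad rgbNorm")
    if (!object@cubeFormat %in% c("envi", "tiff"))
      msg <- c(msg, "bad cubeFormat")
    if (!object@logLevel %in% c("quiet", "info", "debug"))
      msg <- c(msg, "bad logLevel")
    if (is.null(msg)) TRUE else msg
  })

#' Construct a run configuration
#'
#' Defaults equal the module-level defaults everywhere: default phantom,
#' default geometry, automatic S0 floor, clip-with-logging, percentile-99
#' display normalization, ENVI cubes.
#'
#' @param phantom a \linkS4class{PhantomSpec}
#' @param geometry an \linkS4class{InstrumentGeometry}
#' @param s0Floor "auto" or nonnegative number
#' @param clipPolicy "clip", "flag" or "allow"
#' @param rgbNorm "percentile", "per_channel" or "global"
#' @param rgbPercentile percentile for the robust normalization
#' @param cubeFormat "envi" or "tiff"
#' @param outDir output directory for \code{\link{runPipeline}}
#' @param seed master seed; the phantom seed and the acquisition noise seed
#'   are derived from it
#' @param logLevel "quiet", "info" or "debug"
#' @return a \linkS4class{RunConfig}
#' @export
runConfig <- function(phantom = phantomSpec(), geometry = instrumentGeometry(),
                      s0Floor = "auto", clipPolicy = "clip",
                      rgbNorm = "percentile", rgbPercentile = 99,
                      cubeFormat = "envi", outDir = tempfile("polstokes-run"),
                      seed = 1L, logLevel = "info") {
  new("RunConfig", phantom = phantom, geometry = geometry,
      s0Floor = s0Floor, clipPolicy = clipPolicy, rgbNorm = rgbNorm,
      rgbPercentile = rgbPercentile, cubeFormat = cubeFormat,
      outDir = outDir, seed = as.integer(seed), logLevel = logLevel)
}

.configAsList <- function(config) {
  ph <- config@phantom
  g <- config@geometry
  list(
    version = .CONFIG_VERSION,
    seed = config@seed,
    outDir = config@outDir,
    logLevel = config@logLevel,
    geometry = list(polarizer1Axis = g@polarizer1Axis,
                    polarizer2Axis = g@polarizer2Axis,
                    lcvr1FastAxis = g@lcvr1FastAxis,
                    lcvr2FastAxis = g@lcvr2FastAxis),
    phantom = list(imageSize = as.integer(ph@imageSize),
                   nCellsPerClass = as.list(ph@nCellsPerClass),
                   cellRadiusRange = ph@cellRadiusRange,
                   granuleDensity = ph@granuleDensity,
                   granuleDepolContrast = ph@granuleDepolContrast,
                   surfaceTextureAmplitude = ph@surfaceTextureAmplitude,
                   nucleusLobedness = ph@nucleusLobedness,
                   classDepolMean = as.list(ph@classDepolMean),
                   classDepolSD = ph@classDepolSD,
                   depolDispersion = ph@depolDispersion,
                   stainTransmission = ph@stainTransmission,
                   stainUptakeSD = ph@stainUptakeSD,
                   wavelengths = ph@wavelengths,
                   noiseModel = ph@noiseModel,
                   seed = ph@seed,
                   maxPlaceAttempts = ph@maxPlaceAttempts),
    processing = list(s0Floor = config@s0Floor,
                      clipPolicy = config@clipPolicy,
                      rgbNorm = config@rgbNorm,
                      rgbPercentile = config@rgbPercentile,
                      cubeFormat = config@cubeFormat))
}

.checkKeys <- function(x, allowed, where) {
  extra <- setdiff(names(x), allowed)
  if (length(extra))
    stop("unknown config key(s) in ", where, ": ",
         paste(extra, collapse = ", "), call. = FALSE)
}

.configFromList <- function(lst) {
  .checkKeys(lst, c("version", "seed", "outDir", "logLevel", "geometry",
                    "phantom", "processing"), "top level")
  if (!identical(as.integer(lst$version), .CONFIG_VERSION))
    stop("config schema version ", lst$version, " not supported (expect ",
         .CONFIG_VERSION, ")", call. = FALSE)
  g <- lst$geometry %||% list()
  .checkKeys(g, c("polarizer1Axis", "polarizer2Axis", "lcvr1FastAxis",
                  "lcvr2FastAxis"), "geometry")
  geometry <- do.call(instrumentGeometry, g)
  ph <- lst$phantom %||% list()
  .checkKeys(ph, c("imageSize", "nCellsPerClass", "cellRadiusRange",
                   "granuleDensity", "granuleDepolContrast",
                   "surfaceTextureAmplitude", "nucleusLobedness",
                   "classDepolMean", "classDepolSD", "depolDispersion",
                   "stainTransmission", "stainUptakeSD", "wavelengths",
                   "noiseModel", "seed", "maxPlaceAttempts"), "phantom")
  for (nm in c("nCellsPerClass", "classDepolMean"))
    if (!is.null(ph[[nm]])) ph[[nm]] <- unlist(ph[[nm]])
  phantom <- do.call(phantomSpec, ph)
  pr <- lst$processing %||% list()
  .checkKeys(pr, c("s0Floor", "clipPolicy", "rgbNorm", "rgbPercentile",
                   "cubeFormat"), "processing")
  args <- c(list(phantom = phantom, geometry = geometry), pr)
  args$seed <- lst$seed %||% 1L
  args$outDir <- lst$outDir %||% tempfile("polstokes-run")
  args$logLevel <- lst$logLevel %||% "info"
  do.call(runConfig, args)
}

#' Write a run configuration to YAML
#'
#' @param config a \linkS4class{RunConfig}
#' @param path output YAML path
#' @return the path, invisibly
#' @export
writeRunConfig <- function(config, path) {
  stopifnot(is(config, "RunConfig"))
  validObject(config)
  yaml::write_yaml(.configAsList(config), path)
  invisible(path)
}

#' Read a run configuration from YAML
#'
#' The schema is versioned and fail-fast: unknown keys raise an error.
#'
#' @param path YAML path written by \code{\link{writeRunConfig}} (or
#'   authored by hand against the same schema)
#' @return a \linkS4class{RunConfig}
#' @export
readRunConfig <- function(path) {
  .configFromList(yaml::read_yaml(path))
}

## Stable hash of a config: md5 of its canonical JSON rendering, excluding
## run-local fields (output directory, log level) that do not affect the
## numeric results.
configHash <- function(config) {
  lst <- .configAsList(config)
  lst$outDir <- NULL
  lst$logLevel <- NULL
  tf <- tempfile(fileext = ".json")
  on.exit(unlink(tf))
  jsonlite::write_json(lst, tf, auto_unbox = TRUE, digits = NA)
  unname(tools::md5sum(tf))
}
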