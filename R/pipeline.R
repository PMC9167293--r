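## End-to-end orchestration: simulate (or load) -> fit basis -> render the
## three optical stains -> biomarker table, with a hash manifest so that
## identical configurations are verifiably reproducible.

#' Default pipeline configuration
#'
#' Every field has a documented default; \code{\link{runPipeline}} rejects
#' unknown keys. Either \code{simulate} drives the phantom generator, or
#' \code{inputs} points at cube TIFFs with annotations.
#'
#' @param outDir output directory.
#' @param seed master seed; stages derive their randomness from it.
#' @param ... overrides of nested defaults, e.g.
#'   \code{simulate = list(preset = "aggressive")}.
#' @return nested configuration list of class "PipelineConfig".
#' @export
pipelineConfig <- function(outDir = "duvstain-out", seed = 1L, ...) {
  defaults <- list(
    outDir = outDir,
    seed = as.integer(seed),
    simulate = list(
      enabled = TRUE,
      preset = "non_aggressive",
      size = c(192L, 192L),
      nGlands = 8L,
      radiusRange = c(14, 24),
      patientId = "phantom-01"
    ),
    inputs = list(
      cubes = character(0),       # TIFF paths (used when simulate$enabled = FALSE)
      labelMasks = character(0),
      classTables = character(0)
    ),
    pca = list(mode = "transmittance", maxPixels = 500000L),
    stains = list(schemes = c("elevation_123", "azimuth_234", "malignancy_123"),
                  valueClip = c(1, 99)),
    histogram = list(azBins = 360L, elBins = 180L, weight = "count"),
    biomarker = list(threshold = 0),
    logLevel = "info"
  )
  cfg <- utils::modifyList(defaults, list(...))
  .validateConfig(cfg, defaults, "config")
  class(cfg) <- c("PipelineConfig", "list")
  cfg
}

.validateConfig <- function(cfg, defaults, path) {
  unknown <- setdiff(names(cfg), names(defaults))
  if (length(unknown))
    stop("unknown configuration key(s): ",
         paste(paste0(path, "$", unknown), collapse = ", "))
  for (k in names(cfg))
    if (is.list(defaults[[k]]) && !is.null(names(defaults[[k]])))
      .validateConfig(cfg[[k]], defaults[[k]], paste0(path, "$", k))
  invisible(TRUE)
}

#' Read a pipeline configuration from a YAML file
#'
#' @param path YAML file; keys mirror \code{\link{pipelineConfig}}.
#' @param ... further overrides applied on top of the file.
#' @return a validated configuration.
#' @export
readConfig <- function(path, ...) {
  y <- yaml::read_yaml(path)
  extra <- list(...)
  y <- utils::modifyList(y, extra)
  args <- y[intersect(names(y), c("outDir", "seed"))]
  rest <- y[setdiff(names(y), c("outDir", "seed"))]
  do.call(pipelineConfig, c(args, rest))
}

.logmsg <- function(cfg, ...) {
  if (identical(cfg$logLevel, "quiet")) return(invisible(NULL))
  message(sprintf("[duvstain %s] ", format(Sys.time(), "%H:%M:%S")), sprintf(...))
}

#' Run the full optical-stain and biomarker pipeline
#'
#' Stages: (1) simulate a phantom per configuration, or load cubes and
#' annotations from disk; (2) pool spectra and fit the sign-fixed PC basis;
#' (3) render the three optical stains; (4) compute per-class azimuth
#' centers of mass, benign-referenced shifts and the phenotype call;
#' (5) write a manifest with an MD5 hash of every artifact. Any stage
#' failure aborts with a stage-named error.
#'
#' @param config from \code{\link{pipelineConfig}} or \code{\link{readConfig}}.
#' @return the manifest list, invisibly.
#' @export
runPipeline <- function(config = pipelineConfig()) {
  stopifnot(inherits(config, "PipelineConfig"))
  dir.create(config$outDir, showWarnings = FALSE, recursive = TRUE)
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e)
      stop(sprintf("pipeline stage '%s' failed: %s", name, conditionMessage(e)),
           call. = FALSE))
  }
  artifacts <- character(0)

  ## stage 1: inputs
  dat <- stage("inputs", {
    if (isTRUE(config$simulate$enabled)) {
      spec <- phantomSpec(size = config$simulate$size,
                          nGlands = config$simulate$nGlands,
                          radiusRange = config$simulate$radiusRange,
                          preset = config$simulate$preset,
                          seed = config$seed,
                          patientId = config$simulate$patientId)
      ph <- generatePhantom(spec)
      cubePath <- file.path(config$outDir, "cube.tif")
      writeCube(ph$cube, cubePath)
      writeAnnotation(ph$annotation,
                      file.path(config$outDir, "labels.tif"),
                      file.path(config$outDir, "classes.csv"))
      utils::write.csv(ph$truth, file.path(config$outDir, "truth.csv"),
                       row.names = FALSE)
      artifacts <- c(artifacts, "cube.tif", "cube.json", "labels.tif",
                      "classes.csv", "truth.csv")
      list(cubes = list(ph$cube), annotations = list(ph$annotation))
    } else {
      if (!length(config$inputs$cubes)) stop("no input cubes configured")
      cubes <- lapply(config$inputs$cubes, readCube)
      annotations <- Map(readAnnotation, config$inputs$labelMasks,
                         config$inputs$classTables)
      list(cubes = cubes, annotations = unname(annotations))
    }
  })
  .logmsg(config, "inputs ready: %d cube(s)", length(dat$cubes))

  ## stage 2: basis
  basis <- stage("fit-pca", {
    sp <- poolSpectra(dat$cubes, maxPixels = config$pca$maxPixels,
                      seed = config$seed)
    b <- fitPCA(sp, wavelengths = wavelengths(dat$cubes[[1]]),
                mode = config$pca$mode)
    writeBasis(b, file.path(config$outDir, "basis.json"))
    artifacts <- c(artifacts, "basis.json")
    b
  })
  .logmsg(config, "basis fit on %d spectra; EVR %s", basis@fitPixelCount,
          paste(sprintf("%.4f", explainedVariance(basis)), collapse = " "))

  ## stage 3: stains (rendered for the first cube)
  stage("stain", {
    for (sc in config$stains$schemes) {
      scheme <- stainScheme(sc, valueClip = config$stains$valueClip)
      fld <- toSpherical(projectCube(dat$cubes[[1]], basis, pcTriplet(scheme)))
      fn <- paste0("stain_", sc, ".png")
      writeStain(renderStain(fld, scheme), file.path(config$outDir, fn))
      artifacts <- c(artifacts, fn)
    }
  })

  ## stage 4: biomarker
  shifts <- stage("biomarker", {
    fields <- lapply(dat$cubes, function(cb)
      toSpherical(projectCube(cb, basis, c(1L, 2L, 3L))))
    rec <- perClassCoM(fields, dat$annotations,
                       azBins = config$histogram$azBins,
                       elBins = config$histogram$elBins,
                       weight = config$histogram$weight)
    sh <- relativeShifts(rec)
    writeBiomarker(sh, file.path(config$outDir, "biomarker.csv"),
                   threshold = config$biomarker$threshold)
    artifacts <- c(artifacts, "biomarker.csv")
    sh
  })
  .logmsg(config, "biomarker rows: %d", nrow(shifts))

  ## stage 5: manifest
  manifest <- stage("manifest", {
    paths <- file.path(config$outDir, artifacts)
    hashes <- as.character(tools::md5sum(paths))
    ## the hash covers the scientific configuration, not the output location
    cfgStripped <- unclass(config)
    cfgStripped$outDir <- NULL
    m <- list(
      seed = config$seed,
      config_hash = as.character(tools::md5sum(
        {tf <- tempfile(); writeLines(jsonlite::toJSON(cfgStripped, auto_unbox = TRUE, digits = NA), tf); tf})),
      basis_hash = hashes[artifacts == "basis.json"],
      artifacts = stats::setNames(as.list(hashes), artifacts))
    jsonlite::write_json(m, file.path(config$outDir, "manifest.json"),
                         auto_unbox = TRUE, digits = NA)
    m
  })
  .logmsg(config, "done: %d artifacts in %s", length(artifacts), config$outDir)
  invisible(manifest)
}
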