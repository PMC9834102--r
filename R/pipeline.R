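## Pipeline configuration is a named list with blocks:
##   simulation: arguments of simulationConfig() (grid, amplitudes, seed...)
##   input:      paths to an acquired stack and masks instead of simulating
##   paradigm:   arguments of stimulusParadigm()
##   preprocess: register (logical), referenceIndex, detrend (logical)
##   spectral:   vlfMax, excludeStimBinFromVlf, guardBins, window, measure
##   segmentation: kSd, minSize, k, connectivity
##   comparison: quantileType
##   seed:       overrides the simulation block's seed
##   outputDir:  where artifacts and the manifest are written (optional)
## Exactly one of {simulation, input} must be present; unknown keys are
## rejected so a typo fails loudly instead of silently using a default.

pipelineSchema <- list(
  top = c("simulation", "input", "paradigm", "preprocess", "spectral",
          "segmentation", "comparison", "seed", "outputDir"),
  simulation = c("gridRows", "gridCols", "baselineLevel",
                 "activationAmplitude", "responseDelay", "responseTau",
                 "vasomotion", "noiseSd", "driftSlope", "motionMaxShift",
                 "seed", "maskGeometry"),
  input = c("stack", "frameInterval", "trepanation", "psc", "reference"),
  paradigm = c("restDuration", "stimDuration", "cycles", "frameRate"),
  preprocess = c("register", "referenceIndex", "detrend"),
  spectral = c("vlfMax", "excludeStimBinFromVlf", "guardBins", "window",
               "measure"),
  segmentation = c("kSd", "minSize", "k", "connectivity"),
  comparison = c("quantileType")
)

#' Validate a pipeline configuration
#'
#' Checks the block structure described in [runPipeline()]: exactly one of
#' a `simulation` or an `input` block, no unknown keys at any level, and —
#' for an `input` block — that every referenced file exists.
#'
#' @param config named list.
#' @return the config, invisibly, or an error.
#' @export
validatePipelineConfig <- function(config) {
  stopifnot(is.list(config))
  bad <- setdiff(names(config), pipelineSchema$top)
  if (length(bad))
    stop("unknown configuration keys: ", paste(bad, collapse = ", "))
  hasSim <- !is.null(config$simulation)
  hasInput <- !is.null(config$input)
  if (hasSim == hasInput)
    stop("exactly one of a 'simulation' or an 'input' block is required")
  for (block in intersect(names(config), names(pipelineSchema)[-1L])) {
    bad <- setdiff(names(config[[block]]), pipelineSchema[[block]])
    if (length(bad))
      stop("unknown keys in '", block, "' block: ",
           paste(bad, collapse = ", "))
  }
  if (hasInput) {
    need <- c("stack", "trepanation")
    miss <- setdiff(need, names(config$input))
    if (length(miss))
      stop("'input' block must name: ", paste(miss, collapse = ", "))
    for (key in intersect(names(config$input),
                          c("stack", "trepanation", "psc", "reference"))) {
      f <- config$input[[key]]
      if (!file.exists(f)) stop("input file does not exist: ", f)
    }
  }
  invisible(config)
}

#' Read a pipeline configuration file
#'
#' YAML (default) or JSON, selected by file extension.
#'
#' @param path configuration file.
#' @return named list, validated by [validatePipelineConfig()].
#' @export
readPipelineConfig <- function(path) {
  ext <- tolower(tools::file_ext(path))
  config <- if (ext == "json") jsonlite::read_json(path, simplifyVector = TRUE)
  else yaml::read_yaml(path)
  validatePipelineConfig(config)
  config
}

## internal: manifest entry list for a set of files
manifestFiles <- function(paths) {
  lapply(paths, function(p)
    list(file = basename(p), md5 = unname(tools::md5sum(p)),
         bytes = file.size(p)))
}

#' Run the full mapping pipeline
#'
#' Executes the complete chain — simulate (or load) a reflectance stack,
#' preprocess (optional motion compensation, pixelwise detrending), compute
#' the spectral activity map, segment the activation, compare against the
#' reference mask — and, when `outputDir` is set, writes every intermediate
#' (ratio/power maps, all masks, report) together with a manifest listing
#' each file with its MD5 checksum and the parameters used. Identical
#' configuration and seed give byte-identical artifacts.
#'
#' @param config named list, see [validatePipelineConfig()]; file-based
#'   configs load via [readPipelineConfig()].
#' @return list with `report` ([ComparisonReport-class] or `NULL` when no
#'   reference mask is available), `segmentation`, `map`, `sequence`,
#'   `masks`, `truth` (simulation only) and `manifest`.
#' @examples
#' res <- runPipeline(list(
#'   simulation = list(gridRows = 24, gridCols = 24, noiseSd = 0.002),
#'   paradigm = list(cycles = 3),
#'   seed = 1))
#' res$report
#' @export
runPipeline <- function(config) {
  validatePipelineConfig(config)
  paradigm <- do.call(stimulusParadigm, config$paradigm %||% list())

  stage <- "ingest"
  tryCatch({
    if (!is.null(config$simulation)) {
      simArgs <- config$simulation
      if (!is.null(config$seed)) simArgs$seed <- config$seed
      simCfg <- do.call(simulationConfig, c(simArgs, list(paradigm = paradigm)))
      sim <- simulateSequence(simCfg)
      seq <- sim$sequence
      truth <- sim$truth
      masks <- asRegionMaskSet(truth)
    } else {
      inp <- config$input
      seq <- readStack(inp$stack, frameInterval = inp$frameInterval)
      truth <- NULL
      masks <- regionMaskSet(
        trepanation = readMask(inp$trepanation),
        psc = if (!is.null(inp$psc)) readMask(inp$psc),
        referenceActivation = if (!is.null(inp$reference))
          readMask(inp$reference))
    }

    stage <- "preprocess"
    pp <- config$preprocess %||% list()
    if (isTRUE(pp$register))
      seq <- compensateMotion(seq, referenceIndex = pp$referenceIndex %||% 1L)
    if (pp$detrend %||% TRUE)
      seq <- detrendPixelwise(seq)

    stage <- "spectral"
    sp <- config$spectral %||% list()
    map <- computeActivityMap(
      seq, paradigm,
      vlfMax = sp$vlfMax %||% 0.04,
      excludeStimBinFromVlf = sp$excludeStimBinFromVlf %||% TRUE,
      guardBins = sp$guardBins %||% 1L,
      window = sp$window %||% "none",
      measure = sp$measure %||% "power")

    stage <- "segment"
    sg <- config$segmentation %||% list()
    seg <- segmentActivation(
      map, masks@trepanation,
      kSd = sg$kSd %||% 1, minSize = sg$minSize %||% 10,
      k = sg$k %||% 3, connectivity = sg$connectivity %||% 8)

    stage <- "compare"
    report <- if (!is.null(masks@referenceActivation))
      compareToReference(map, seg, masks,
                         quantileType = config$comparison$quantileType %||% 7)
    else NULL

    stage <- "write"
    manifest <- NULL
    if (!is.null(config$outputDir)) {
      dir <- config$outputDir
      dir.create(dir, recursive = TRUE, showWarnings = FALSE)
      paths <- writeActivityMap(map, dir)
      maskPaths <- c(
        thresholded = file.path(dir, "thresholded.png"),
        opened = file.path(dir, "opened.png"),
        activation = file.path(dir, "activation.png"),
        hull = file.path(dir, "hull.png"),
        trepanation = file.path(dir, "trepanation.png"))
      writeMask(seg@thresholdedMap, maskPaths["thresholded"])
      writeMask(seg@openedMap, maskPaths["opened"])
      writeMask(seg@activation, maskPaths["activation"])
      writeMask(seg@hull, maskPaths["hull"])
      writeMask(masks@trepanation, maskPaths["trepanation"])
      if (!is.null(masks@psc)) {
        maskPaths["psc"] <- file.path(dir, "psc.png")
        writeMask(masks@psc, maskPaths["psc"])
      }
      if (!is.null(masks@referenceActivation)) {
        maskPaths["reference"] <- file.path(dir, "reference.png")
        writeMask(masks@referenceActivation, maskPaths["reference"])
      }
      reportPath <- character()
      if (!is.null(report)) {
        reportPath <- file.path(dir, "report.json")
        writeReport(report, reportPath,
                    extra = list(z_thresh = seg@zThresh,
                                 components = seg@components))
      }
      allFiles <- c(paths[c("ratio", "p_s", "p_vlf", "meta")],
                    paste0(paths[c("ratio", "p_s", "p_vlf")], ".json"),
                    maskPaths, reportPath)
      manifest <- list(
        package = "ioimap",
        version = as.character(utils::packageVersion("ioimap")),
        parameters = config[setdiff(names(config), "outputDir")],
        files = manifestFiles(unname(allFiles)))
      jsonlite::write_json(manifest, file.path(dir, "manifest.json"),
                           auto_unbox = TRUE, digits = NA)
    }

    list(report = report, segmentation = seg, map = map, sequence = seq,
         masks = masks, truth = truth, manifest = manifest)
  }, error = function(e) {
    stop("pipeline stage '", stage, "' failed: ", conditionMessage(e),
         call. = FALSE)
  })
}

`%||%` <- function(a, b) if (is.null(a)) b else a
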