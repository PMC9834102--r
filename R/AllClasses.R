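#' @import methods
NULL

setClassUnion("matrixOrNULL", c("matrix", "NULL"))

#' Block-design stimulation paradigm
#'
#' Describes the rest/stimulation block design driving the cortical
#' measurement: alternating rest and stimulation epochs of fixed duration,
#' repeated for a given number of cycles and sampled at a fixed frame rate.
#' The paradigm determines the fundamental stimulation frequency
#' \eqn{f_{stim} = 1/(T_{rest} + T_{stim})} and the total number of frames in
#' a recording.
#'
#' @slot restDuration rest epoch duration in seconds.
#' @slot stimDuration stimulation epoch duration in seconds.
#' @slot cycles number of rest+stimulation cycles.
#' @slot frameRate acquisition rate in frames per second.
#'
#' @seealso [stimulusParadigm()], [totalFrames()], [stimFrequency()]
#' @exportClass StimulusParadigm
setClass("StimulusParadigm",
  representation(
    restDuration = "numeric",
    stimDuration = "numeric",
    cycles = "numeric",
    frameRate = "numeric"
  )
)

setValidity("StimulusParadigm", function(object) {
  msg <- character()
  for (s in c("restDuration", "stimDuration", "cycles", "frameRate")) {
    v <- slot(object, s)
    if (length(v) != 1L || !is.finite(v) || v <= 0)
      msg <- c(msg, sprintf("'%s' must be a single positive finite number", s))
  }
  if (!length(msg)) {
    if (abs(object@cycles - round(object@cycles)) > 1e-9)
      msg <- c(msg, "'cycles' must be an integer count")
    nf <- object@frameRate * (object@restDuration + object@stimDuration)
    if (abs(nf - round(nf)) > 1e-9)
      msg <- c(msg, sprintf(
        "frameRate * (restDuration + stimDuration) = %.6g is not an integer; each cycle must contain a whole number of frames",
        nf))
  }
  if (length(msg)) msg else TRUE
})

#' Cortical reflectance image time series
#'
#' A (time x rows x cols) stack of real-valued reflectance frames together
#' with its frame interval, the provenance of the intensity channel and an
#' ordered log of preprocessing steps already applied. This is the raw
#' material of all spectral mapping.
#'
#' @slot frames numeric array, time x rows x cols.
#' @slot frameInterval seconds between consecutive frames (> 0).
#' @slot channelOrigin one of `"filtered_568nm"`, `"rgb_green"`, `"synthetic"`.
#' @slot processingLog character vector, one entry per applied step.
#'
#' @seealso [reflectanceSequence()], [frames()], [detrendPixelwise()]
#' @exportClass ReflectanceSequence
setClass("ReflectanceSequence",
  representation(
    frames = "array",
    frameInterval = "numeric",
    channelOrigin = "character",
    processingLog = "character"
  )
)

setValidity("ReflectanceSequence", function(object) {
  msg <- character()
  if (length(dim(object@frames)) != 3L)
    msg <- c(msg, "'frames' must be a 3-D array (time x rows x cols)")
  if (!all(is.finite(object@frames)))
    msg <- c(msg, "'frames' must contain only finite values")
  if (length(object@frameInterval) != 1L || !is.finite(object@frameInterval) ||
      object@frameInterval <= 0)
    msg <- c(msg, "'frameInterval' must be a single positive number")
  ok <- c("filtered_568nm", "rgb_green", "synthetic")
  if (length(object@channelOrigin) != 1L || !object@channelOrigin %in% ok)
    msg <- c(msg, paste0("'channelOrigin' must be one of ",
                         paste(ok, collapse = ", ")))
  if (length(msg)) msg else TRUE
})

#' Configuration of the synthetic cortical reflectance simulator
#'
#' Bundles every knob of the synthetic scene: grid size, paradigm, baseline
#' reflectance, stimulation-locked response (fractional amplitude, onset
#' delay, exponential time constant), global vasomotion sinusoids, white
#' noise, slow drift, optional frame-to-frame translation, the random seed
#' and the geometry of the ground-truth masks.
#'
#' @slot gridRows,gridCols spatial grid size in pixels.
#' @slot paradigm a [StimulusParadigm-class].
#' @slot baselineLevel mean reflectance in arbitrary units (> 0).
#' @slot activationAmplitude fractional reflectance change at the stimulation
#'   plateau; negative for the absorption increase that accompanies a rise in
#'   cerebral blood volume at 568 nm.
#' @slot responseDelay hemodynamic onset lag in seconds.
#' @slot responseTau exponential rise/decay time constant in seconds.
#' @slot vasomotion data frame with columns `frequency` (Hz, all < 0.04),
#'   `amplitude` (fractional) and `phase` (rad); one row per global
#'   vasomotion sinusoid.
#' @slot noiseSd fractional standard deviation of i.i.d. Gaussian pixel noise.
#' @slot driftSlope fractional reflectance change per minute (linear drift).
#' @slot motionMaxShift maximum absolute per-frame translation in pixels
#'   (integer shifts; 0 disables motion).
#' @slot seed integer seed governing all randomness.
#' @slot maskGeometry named list of ground-truth mask geometry parameters,
#'   see [simulationConfig()].
#'
#' @seealso [simulationConfig()], [simulateSequence()]
#' @exportClass SimulationConfig
setClass("SimulationConfig",
  representation(
    gridRows = "numeric",
    gridCols = "numeric",
    paradigm = "StimulusParadigm",
    baselineLevel = "numeric",
    activationAmplitude = "numeric",
    responseDelay = "numeric",
    responseTau = "numeric",
    vasomotion = "data.frame",
    noiseSd = "numeric",
    driftSlope = "numeric",
    motionMaxShift = "numeric",
    seed = "numeric",
    maskGeometry = "list"
  )
)

setValidity("SimulationConfig", function(object) {
  msg <- character()
  if (object@gridRows < 8 || object@gridCols < 8)
    msg <- c(msg, "grid must be at least 8 x 8 pixels")
  if (!is.finite(object@baselineLevel) || object@baselineLevel <= 0)
    msg <- c(msg, "'baselineLevel' must be positive")
  for (s in c("activationAmplitude", "noiseSd", "driftSlope"))
    if (!is.finite(slot(object, s)))
      msg <- c(msg, sprintf("'%s' must be finite", s))
  if (object@noiseSd < 0) msg <- c(msg, "'noiseSd' must be >= 0")
  if (object@responseTau <= 0) msg <- c(msg, "'responseTau' must be > 0")
  if (object@responseDelay < 0) msg <- c(msg, "'responseDelay' must be >= 0")
  vm <- object@vasomotion
  need <- c("frequency", "amplitude", "phase")
  if (!all(need %in% names(vm)))
    msg <- c(msg, "'vasomotion' needs columns frequency, amplitude, phase")
  else if (nrow(vm) && any(vm$frequency >= 0.04))
    msg <- c(msg, "every vasomotion frequency must lie below 0.04 Hz")
  if (object@motionMaxShift < 0 ||
      abs(object@motionMaxShift - round(object@motionMaxShift)) > 1e-9)
    msg <- c(msg, "'motionMaxShift' must be a non-negative integer")
  if (length(object@seed) != 1L || !is.finite(object@seed))
    msg <- c(msg, "'seed' must be a single integer")
  if (length(msg)) msg else TRUE
})

#' Ground truth of a simulated scene
#'
#' Binary masks marking where the stimulation-locked signal was injected
#' (activation), the simulated primary sensory cortex band (PSC) and the
#' trepanation window, plus the per-pixel injected fractional amplitude.
#' The masks nest: activation within PSC within trepanation.
#'
#' @slot activationMask,pscMask,trepanationMask logical matrices on the
#'   simulation grid.
#' @slot amplitudeMap numeric matrix of injected fractional amplitudes.
#'
#' @exportClass SimulationTruth
setClass("SimulationTruth",
  representation(
    activationMask = "matrix",
    pscMask = "matrix",
    trepanationMask = "matrix",
    amplitudeMap = "matrix"
  )
)

setValidity("SimulationTruth", function(object) {
  msg <- character()
  d <- dim(object@trepanationMask)
  if (!identical(dim(object@activationMask), d) ||
      !identical(dim(object@pscMask), d) ||
      !identical(dim(object@amplitudeMap), d))
    msg <- c(msg, "all truth masks must share one spatial grid")
  else {
    if (any(object@activationMask & !object@pscMask))
      msg <- c(msg, "activation mask must lie within the PSC mask")
    if (any(object@pscMask & !object@trepanationMask))
      msg <- c(msg, "PSC mask must lie within the trepanation mask")
  }
  if (length(msg)) msg else TRUE
})

#' Spectral activity map
#'
#' The per-pixel ratio of stimulation-frequency power to summed
#' very-low-frequency vasomotion power, together with its two constituent
#' maps and the spectral bookkeeping (stimulation frequency, VLF band,
#' frequency-bin indices excluded from the VLF sum).
#'
#' @slot ratio rows x cols map of stimulation power over VLF power.
#' @slot pS rows x cols one-sided power at the stimulation-frequency bin.
#' @slot pVLF rows x cols summed one-sided power over the VLF band.
#' @slot fStim stimulation frequency in Hz.
#' @slot vlfBand numeric length 2, the half-open VLF frequency interval.
#' @slot excludedBins integer DFT bin indices (0-based) removed from the
#'   VLF sum (always the DC bin; by default also the stimulation bin and its
#'   one-bin guard on either side).
#' @slot zeroDenominatorCount number of pixels whose VLF power was zero
#'   (their ratio is reported as 0).
#' @slot freqResolution DFT bin spacing in Hz.
#'
#' @seealso [computeActivityMap()], [ratioMap()]
#' @exportClass ActivityMap
setClass("ActivityMap",
  representation(
    ratio = "matrix",
    pS = "matrix",
    pVLF = "matrix",
    fStim = "numeric",
    vlfBand = "numeric",
    excludedBins = "integer",
    zeroDenominatorCount = "integer",
    freqResolution = "numeric"
  )
)

setValidity("ActivityMap", function(object) {
  msg <- character()
  d <- dim(object@ratio)
  if (!identical(dim(object@pS), d) || !identical(dim(object@pVLF), d))
    msg <- c(msg, "ratio, pS and pVLF must share one spatial grid")
  if (!all(is.finite(object@ratio)) || any(object@ratio < 0) ||
      !all(is.finite(object@pS)) || any(object@pS < 0) ||
      !all(is.finite(object@pVLF)) || any(object@pVLF < 0))
    msg <- c(msg, "all maps must be finite and non-negative")
  if (length(object@vlfBand) != 2L || object@vlfBand[1] >= object@vlfBand[2])
    msg <- c(msg, "'vlfBand' must be an increasing (f_min, f_max) pair")
  if (length(msg)) msg else TRUE
})

#' Set of anatomical region masks
#'
#' Binary masks on the activity-map grid: the trepanation (craniotomy)
#' window — the domain of all statistics —, optionally the primary sensory
#' cortex (PSC) segmentation and optionally a reference activation mask
#' (typically fMRI-derived). PSC and reference masks are expected to lie
#' within the trepanation; violations are reported as warnings at
#' construction and the masks are used as given.
#'
#' @slot trepanation logical matrix.
#' @slot psc logical matrix or NULL.
#' @slot referenceActivation logical matrix or NULL.
#'
#' @seealso [regionMaskSet()], [regionStatistics()]
#' @exportClass RegionMaskSet
setClass("RegionMaskSet",
  representation(
    trepanation = "matrix",
    psc = "matrixOrNULL",
    referenceActivation = "matrixOrNULL"
  )
)

setValidity("RegionMaskSet", function(object) {
  msg <- character()
  d <- dim(object@trepanation)
  if (!is.logical(object@trepanation))
    msg <- c(msg, "'trepanation' must be a logical matrix")
  if (!is.null(object@psc) && !identical(dim(object@psc), d))
    msg <- c(msg, "'psc' must share the trepanation grid")
  if (!is.null(object@referenceActivation) &&
      !identical(dim(object@referenceActivation), d))
    msg <- c(msg, "'referenceActivation' must share the trepanation grid")
  if (length(msg)) msg else TRUE
})

#' Segmented activation of an activity map
#'
#' Records the full segmentation chain: the mean-plus-SD threshold value,
#' the thresholded map restricted to the trepanation, the map after
#' small-component removal, the union of the k largest connected components
#' (the activation area), the component table and the rasterized convex
#' hull of the activation. The masks nest: activation within opened within
#' thresholded within trepanation.
#'
#' @slot zThresh threshold in ratio units (trepanation mean + k_sd * SD).
#' @slot thresholdedMap,openedMap,activation,hull logical matrices.
#' @slot components data frame with columns `label`, `size`,
#'   `centroidRow`, `centroidCol`, `firstIndex`, `selected`.
#' @slot parameters named list of the segmentation parameters used.
#'
#' @seealso [segmentActivation()], [thresholdActivity()]
#' @exportClass ActivationSegmentation
setClass("ActivationSegmentation",
  representation(
    zThresh = "numeric",
    thresholdedMap = "matrix",
    openedMap = "matrix",
    activation = "matrix",
    hull = "matrix",
    components = "data.frame",
    parameters = "list"
  )
)

setValidity("ActivationSegmentation", function(object) {
  msg <- character()
  d <- dim(object@thresholdedMap)
  if (!identical(dim(object@openedMap), d) ||
      !identical(dim(object@activation), d) ||
      !identical(dim(object@hull), d))
    msg <- c(msg, "all segmentation masks must share one grid")
  else {
    if (any(object@activation & !object@openedMap))
      msg <- c(msg, "activation must be a subset of the opened map")
    if (any(object@openedMap & !object@thresholdedMap))
      msg <- c(msg, "opened map must be a subset of the thresholded map")
    if (any(object@activation & !object@hull))
      msg <- c(msg, "hull must contain the activation")
  }
  if (length(msg)) msg else TRUE
})

#' Quantitative comparison of an activation segmentation with a reference
#'
#' Holds the three DICE similarity coefficients of the paper-style triplet
#' (segmented activation, its convex hull, and the complete thresholded map,
#' each against the reference mask clipped to the trepanation) and
#' region-restricted quartile statistics of the raw activity-map values.
#'
#' @slot diceActivation,diceHull,diceFull DICE coefficients in [0, 1].
#' @slot regionStats data frame with one row per region
#'   (`reference_activation`, `psc_minus_reference`, `surrounding`) and
#'   columns `region`, `n`, `median`, `q1`, `q3`.
#' @slot notes character vector of warnings accumulated while comparing.
#'
#' @seealso [diceTriplet()], [regionStatistics()], [runPipeline()]
#' @exportClass ComparisonReport
setClass("ComparisonReport",
  representation(
    diceActivation = "numeric",
    diceHull = "numeric",
    diceFull = "numeric",
    regionStats = "data.frame",
    notes = "character"
  )
)

setValidity("ComparisonReport", function(object) {
  msg <- character()
  for (s in c("diceActivation", "diceHull", "diceFull")) {
    v <- slot(object, s)
    if (length(v) && (!is.finite(v) || v < 0 || v > 1))
      msg <- c(msg, sprintf("'%s' must lie in [0, 1]", s))
  }
  if (length(msg)) msg else TRUE
})

#' Topographic composition of several stimulation sites
#'
#' An integer label map assembling the segmented activation of every
#' stimulation site into one image (0 = background, i = site i), the ordered
#' site names, the policy used to resolve pixels claimed by several sites,
#' the pairwise site-overlap DICE matrix and the untouched per-site masks.
#'
#' @slot labelMap integer matrix.
#' @slot siteNames character vector of site labels, in composition order.
#' @slot overlapPolicy description of the multi-site resolution rule.
#' @slot overlapDice symmetric matrix of pairwise DICE coefficients.
#' @slot siteMasks named list of the original per-site logical masks.
#'
#' @seealso [composeTopography()]
#' @exportClass TopographicMap
setClass("TopographicMap",
  representation(
    labelMap = "matrix",
    siteNames = "character",
    overlapPolicy = "character",
    overlapDice = "matrix",
    siteMasks = "list"
  )
)

setValidity("TopographicMap", function(object) {
  msg <- character()
  n <- length(object@siteNames)
  if (anyDuplicated(object@siteNames))
    msg <- c(msg, "site names must be unique")
  if (any(!object@labelMap %in% 0:n))
    msg <- c(msg, "label map values must lie in {0, ..., n_sites}")
  if (length(object@siteMasks) != n)
    msg <- c(msg, "one mask per site required")
  if (length(msg)) msg else TRUE
})
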