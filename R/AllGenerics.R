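#' Accessors for ioimap classes
#'
#' Small accessor generics so user code never reaches into slots:
#' `frames()` returns the (time x rows x cols) array of a
#' [ReflectanceSequence-class]; `frameInterval()`, `channelOrigin()` and
#' `processingLog()` its metadata; `nFrames()` its length;
#' `totalFrames()` and `stimFrequency()` the derived quantities of a
#' [StimulusParadigm-class]; `ratioMap()`, `stimPower()` and `vlfPower()`
#' the constituent maps of an [ActivityMap-class]; `activationMask()` the
#' segmented activation (or injected truth) mask; `hullMask()` its convex
#' hull; `componentTable()` the connected-component table of an
#' [ActivationSegmentation-class]; `diceValues()` the named DICE triplet and
#' `regionStats()` the per-region quartile table of a
#' [ComparisonReport-class].
#'
#' @param x an ioimap object.
#' @return The slot value or derived quantity named by the generic.
#' @name accessors
NULL

#' @rdname accessors
#' @export
setGeneric("frames", function(x) standardGeneric("frames"))
#' @rdname accessors
#' @export
setGeneric("frameInterval", function(x) standardGeneric("frameInterval"))
#' @rdname accessors
#' @export
setGeneric("channelOrigin", function(x) standardGeneric("channelOrigin"))
#' @rdname accessors
#' @export
setGeneric("processingLog", function(x) standardGeneric("processingLog"))
#' @rdname accessors
#' @export
setGeneric("nFrames", function(x) standardGeneric("nFrames"))
#' @rdname accessors
#' @export
setGeneric("totalFrames", function(x) standardGeneric("totalFrames"))
#' @rdname accessors
#' @export
setGeneric("stimFrequency", function(x) standardGeneric("stimFrequency"))
#' @rdname accessors
#' @export
setGeneric("ratioMap", function(x) standardGeneric("ratioMap"))
#' @rdname accessors
#' @export
setGeneric("stimPower", function(x) standardGeneric("stimPower"))
#' @rdname accessors
#' @export
setGeneric("vlfPower", function(x) standardGeneric("vlfPower"))
#' @rdname accessors
#' @export
setGeneric("activationMask", function(x) standardGeneric("activationMask"))
#' @rdname accessors
#' @export
setGeneric("hullMask", function(x) standardGeneric("hullMask"))
#' @rdname accessors
#' @export
setGeneric("componentTable", function(x) standardGeneric("componentTable"))
#' @rdname accessors
#' @export
setGeneric("diceValues", function(x) standardGeneric("diceValues"))
#' @rdname accessors
#' @export
setGeneric("regionStats", function(x) standardGeneric("regionStats"))

#' @rdname accessors
setMethod("frames", "ReflectanceSequence", function(x) x@frames)
#' @rdname accessors
setMethod("frameInterval", "ReflectanceSequence", function(x) x@frameInterval)
#' @rdname accessors
setMethod("channelOrigin", "ReflectanceSequence", function(x) x@channelOrigin)
#' @rdname accessors
setMethod("processingLog", "ReflectanceSequence", function(x) x@processingLog)
#' @rdname accessors
setMethod("nFrames", "ReflectanceSequence", function(x) dim(x@frames)[1L])

#' @rdname accessors
setMethod("totalFrames", "StimulusParadigm", function(x) {
  as.integer(round(x@cycles * (x@restDuration + x@stimDuration) * x@frameRate))
})
#' @rdname accessors
setMethod("stimFrequency", "StimulusParadigm", function(x) {
  1 / (x@restDuration + x@stimDuration)
})
#' @rdname accessors
setMethod("stimFrequency", "ActivityMap", function(x) x@fStim)

#' @rdname accessors
setMethod("ratioMap", "ActivityMap", function(x) x@ratio)
#' @rdname accessors
setMethod("stimPower", "ActivityMap", function(x) x@pS)
#' @rdname accessors
setMethod("vlfPower", "ActivityMap", function(x) x@pVLF)

#' @rdname accessors
setMethod("activationMask", "ActivationSegmentation", function(x) x@activation)
#' @rdname accessors
setMethod("activationMask", "SimulationTruth", function(x) x@activationMask)
#' @rdname accessors
setMethod("hullMask", "ActivationSegmentation", function(x) x@hull)
#' @rdname accessors
setMethod("componentTable", "ActivationSegmentation", function(x) x@components)

#' @rdname accessors
setMethod("diceValues", "ComparisonReport", function(x) {
  c(activation = x@diceActivation, hull = x@diceHull, full = x@diceFull)
})
#' @rdname accessors
setMethod("regionStats", "ComparisonReport", function(x) x@regionStats)

setMethod("show", "StimulusParadigm", function(object) {
  cat(sprintf(
    "StimulusParadigm: %g cycles of %g s rest + %g s stimulation at %g fps\n",
    object@cycles, object@restDuration, object@stimDuration,
    object@frameRate))
  cat(sprintf("  f_stim = %.5g Hz, %d frames total\n",
              stimFrequency(object), totalFrames(object)))
})

setMethod("show", "ReflectanceSequence", function(object) {
  d <- dim(object@frames)
  cat(sprintf(
    "ReflectanceSequence: %d frames of %d x %d pixels (%.3g s interval, %s)\n",
    d[1], d[2], d[3], object@frameInterval, object@channelOrigin))
  if (length(object@processingLog))
    cat("  steps:", paste(object@processingLog, collapse = " -> "), "\n")
})

setMethod("show", "ActivityMap", function(object) {
  d <- dim(object@ratio)
  cat(sprintf("ActivityMap: %d x %d pixels\n", d[1], d[2]))
  cat(sprintf("  f_stim = %.5g Hz, VLF band (%g, %g) Hz, %d bins excluded\n",
              object@fStim, object@vlfBand[1], object@vlfBand[2],
              length(object@excludedBins)))
  cat(sprintf("  ratio range [%.4g, %.4g]; %d zero-denominator pixels\n",
              min(object@ratio), max(object@ratio),
              object@zeroDenominatorCount))
})

setMethod("show", "ActivationSegmentation", function(object) {
  cat(sprintf(
    "ActivationSegmentation: z_thresh = %.4g; %d supra-threshold px -> %d after opening -> %d in activation (%d component%s)\n",
    object@zThresh, sum(object@thresholdedMap), sum(object@openedMap),
    sum(object@activation), sum(object@components$selected),
    if (sum(object@components$selected) == 1L) "" else "s"))
})

setMethod("show", "ComparisonReport", function(object) {
  cat("ComparisonReport\n")
  cat(sprintf("  DICE activation/hull/full: %.3f / %.3f / %.3f\n",
              object@diceActivation, object@diceHull, object@diceFull))
  if (nrow(object@regionStats)) {
    cat("  region statistics (median [Q1, Q3], n):\n")
    for (i in seq_len(nrow(object@regionStats))) {
      r <- object@regionStats[i, ]
      cat(sprintf("    %-22s %.3g [%.3g, %.3g], n = %d\n",
                  r$region, r$median, r$q1, r$q3, r$n))
    }
  }
})

setMethod("show", "TopographicMap", function(object) {
  cat(sprintf("TopographicMap: %d sites (%s) on %d x %d grid\n",
              length(object@siteNames),
              paste(object@siteNames, collapse = ", "),
              nrow(object@labelMap), ncol(object@labelMap)))
  cat(sprintf("  overlap policy: %s\n", object@overlapPolicy))
})

setMethod("show", "SimulationTruth", function(object) {
  cat(sprintf(
    "SimulationTruth: %d x %d grid; trepanation %d px, PSC %d px, activation %d px\n",
    nrow(object@trepanationMask), ncol(object@trepanationMask),
    sum(object@trepanationMask), sum(object@pscMask),
    sum(object@activationMask)))
})

setMethod("show", "SimulationConfig", function(object) {
  cat(sprintf("SimulationConfig: %g x %g grid, seed %g\n",
              object@gridRows, object@gridCols, object@seed))
  show(object@paradigm)
  cat(sprintf(
    "  amplitude %.3g, delay %g s, tau %g s; noise SD %.3g, drift %.3g/min, %d vasomotion component%s\n",
    object@activationAmplitude, object@responseDelay, object@responseTau,
    object@noiseSd, object@driftSlope, nrow(object@vasomotion),
    if (nrow(object@vasomotion) == 1L) "" else "s"))
})
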