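#' Construct a block-design stimulation paradigm
#'
#' @param restDuration rest epoch in seconds (default 30).
#' @param stimDuration stimulation epoch in seconds (default 30).
#' @param cycles number of rest+stimulation cycles (default 9).
#' @param frameRate frames per second (default 2). Must divide each cycle
#'   into a whole number of frames.
#'
#' @details The default paradigm — 9 cycles of 30 s rest followed by 30 s
#' stimulation — gives a stimulation frequency of 1/60 Hz and, at 2 fps,
#' 1080 frames over 9 minutes. Because the recording spans an integer number
#' of stimulation cycles, the stimulation frequency falls exactly on DFT bin
#' number `cycles`, which is what makes window-free spectral mapping exact.
#'
#' @return A [StimulusParadigm-class] object.
#' @examples
#' p <- stimulusParadigm()
#' totalFrames(p)    # 1080
#' stimFrequency(p)  # 1/60 Hz
#' @export
stimulusParadigm <- function(restDuration = 30, stimDuration = 30,
                             cycles = 9, frameRate = 2) {
  new("StimulusParadigm", restDuration = restDuration,
      stimDuration = stimDuration, cycles = cycles, frameRate = frameRate)
}

#' Construct a reflectance sequence from a frame array
#'
#' @param frames numeric array, time x rows x cols.
#' @param frameInterval seconds between frames.
#' @param channelOrigin provenance of the intensity channel:
#'   `"filtered_568nm"`, `"rgb_green"` or `"synthetic"`.
#' @param processingLog optional character vector of steps already applied.
#' @return A [ReflectanceSequence-class] object. Intensities are stored as
#'   doubles; integer camera data (8- or 12-bit) are not rescaled because
#'   the downstream power ratio is invariant to global gain.
#' @export
reflectanceSequence <- function(frames, frameInterval,
                                channelOrigin = "synthetic",
                                processingLog = character()) {
  storage.mode(frames) <- "double"
  new("ReflectanceSequence", frames = frames, frameInterval = frameInterval,
      channelOrigin = channelOrigin, processingLog = processingLog)
}

## internal: append a step to the log, returning a modified copy
logStep <- function(seq, step) {
  seq@processingLog <- c(seq@processingLog, step)
  seq
}
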