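#' Default vasomotion component table
#'
#' Three global vasomotion sinusoids at 0.008, 0.015 and 0.03 Hz with a
#' fractional amplitude of 0.005 each and fixed, distinct phases. All
#' frequencies lie below the 0.04 Hz vasomotion band edge.
#'
#' @return data frame with columns `frequency`, `amplitude`, `phase`.
#' @export
defaultVasomotion <- function() {
  data.frame(
    frequency = c(0.008, 0.015, 0.03),
    amplitude = c(0.005, 0.005, 0.005),
    phase     = c(0, 2.1, 4.4)
  )
}

#' Default geometry of the synthetic ground-truth masks
#'
#' All sizes are fractions of the shorter grid side so the scene scales with
#' grid resolution: the trepanation is a centred disc, the PSC a straight
#' oblique band crossing it, and the activation an ellipse centred on the
#' band axis (offset along the band by `activationOffsetFrac`).
#'
#' @return named list of geometry parameters.
#' @export
defaultMaskGeometry <- function() {
  list(
    trepanationRadiusFrac = 0.42,
    bandHalfWidthFrac     = 0.08,
    bandAngleDeg          = 30,
    activationSemiMajorFrac = 0.095,
    activationSemiMinorFrac = 0.055,
    activationOffsetFrac    = 0
  )
}

#' Configure the synthetic cortical reflectance simulator
#'
#' Builds a validated [SimulationConfig-class]. The defaults define the
#' reference synthetic scenario used throughout the package tests: a
#' 128 x 128 grid, 9 cycles of 30 s rest + 30 s stimulation at 2 fps,
#' a 2\% reflectance decrease at the stimulation plateau (negative sign:
#' increased absorption with increased cerebral blood volume at 568 nm),
#' hemodynamic onset delay 2 s with a 5 s exponential time constant, three
#' sub-0.04 Hz vasomotion sinusoids at 0.5\% amplitude, 0.5\% white noise,
#' a 0.2\%-per-minute linear drift and no frame-to-frame motion.
#'
#' @param gridRows,gridCols grid size in pixels.
#' @param paradigm a [StimulusParadigm-class].
#' @param baselineLevel mean reflectance (arbitrary units, > 0).
#' @param activationAmplitude fractional plateau change inside the
#'   activation mask (negative for a reflectance decrease).
#' @param responseDelay,responseTau hemodynamic onset lag and exponential
#'   rise/decay constant, seconds.
#' @param vasomotion data frame (`frequency` Hz < 0.04, `amplitude`, `phase`).
#' @param noiseSd fractional SD of i.i.d. Gaussian pixel noise.
#' @param driftSlope fractional change per minute (global linear drift).
#' @param motionMaxShift maximum per-frame integer translation (pixels).
#' @param seed integer seed governing all randomness.
#' @param maskGeometry list as returned by [defaultMaskGeometry()]; missing
#'   entries are filled with the defaults.
#' @return A [SimulationConfig-class].
#' @examples
#' cfg <- simulationConfig(gridRows = 32, gridCols = 32, seed = 1)
#' @export
simulationConfig <- function(gridRows = 128, gridCols = 128,
                             paradigm = stimulusParadigm(),
                             baselineLevel = 1,
                             activationAmplitude = -0.02,
                             responseDelay = 2, responseTau = 5,
                             vasomotion = defaultVasomotion(),
                             noiseSd = 0.005,
                             driftSlope = 0.002,
                             motionMaxShift = 0,
                             seed = 0,
                             maskGeometry = defaultMaskGeometry()) {
  geom <- defaultMaskGeometry()
  geom[names(maskGeometry)] <- maskGeometry
  new("SimulationConfig",
      gridRows = gridRows, gridCols = gridCols, paradigm = paradigm,
      baselineLevel = baselineLevel,
      activationAmplitude = activationAmplitude,
      responseDelay = responseDelay, responseTau = responseTau,
      vasomotion = vasomotion, noiseSd = noiseSd, driftSlope = driftSlope,
      motionMaxShift = motionMaxShift, seed = seed, maskGeometry = geom)
}

## internal: ground-truth masks from the configured geometry
buildTruthMasks <- function(config) {
  R <- config@gridRows; C <- config@gridCols
  g <- config@maskGeometry
  short <- min(R, C)
  cr <- (R + 1) / 2; cc <- (C + 1) / 2
  rows <- matrix(seq_len(R), R, C)
  cols <- matrix(seq_len(C), R, C, byrow = TRUE)

  trep <- (rows - cr)^2 + (cols - cc)^2 <= (g$trepanationRadiusFrac * short)^2

  th <- g$bandAngleDeg * pi / 180
  dr <- cos(th); dc <- sin(th)       # band axis direction (row, col)
  nr <- -dc; nc <- dr                # band normal
  along  <- (rows - cr) * dr + (cols - cc) * dc
  across <- (rows - cr) * nr + (cols - cc) * nc
  psc <- abs(across) <= g$bandHalfWidthFrac * short
  psc <- psc & trep

  off <- g$activationOffsetFrac * short
  a <- g$activationSemiMajorFrac * short
  b <- g$activationSemiMinorFrac * short
  act <- ((along - off) / a)^2 + (across / b)^2 <= 1
  act <- act & psc

  amp <- matrix(0, R, C)
  amp[act] <- config@activationAmplitude

  new("SimulationTruth", activationMask = act, pscMask = psc,
      trepanationMask = trep, amplitudeMap = amp)
}

## internal: per-frame hemodynamic response in [0, 1] — a rest/stimulation
## box-car delayed by responseDelay, passed through a first-order
## exponential lag (exact zero-order-hold discretization)
responseWaveform <- function(paradigm, responseDelay, responseTau) {
  n <- totalFrames(paradigm)
  dt <- 1 / paradigm@frameRate
  t <- (seq_len(n) - 1L) * dt
  cyc <- paradigm@restDuration + paradigm@stimDuration
  td <- t - responseDelay
  s <- as.numeric(td >= 0 & (td %% cyc) >= paradigm@restDuration)
  alpha <- 1 - exp(-dt / responseTau)
  r <- numeric(n)
  for (i in seq_len(n)[-1L]) r[i] <- r[i - 1L] + alpha * (s[i] - r[i - 1L])
  r
}

## internal: translate one frame by integer (dy, dx), exposed border filled
## with the frame median
shiftFrame <- function(m, dy, dx, fill = stats::median(m)) {
  R <- nrow(m); C <- ncol(m)
  out <- matrix(fill, R, C)
  srcR <- seq_len(R) - dy; srcC <- seq_len(C) - dx
  okR <- srcR >= 1L & srcR <= R; okC <- srcC >= 1L & srcC <= C
  out[okR, okC] <- m[srcR[okR], srcC[okC]]
  out
}

#' Simulate a cortical reflectance sequence with known ground truth
#'
#' Generates a seeded synthetic recording of a block-design measurement.
#' Inside the ground-truth activation mask the reflectance follows
#' `baseline * (1 + amplitude * r(t))` where `r(t)` is the paradigm box-car
#' delayed by `responseDelay` and filtered by a first-order exponential lag
#' with time constant `responseTau`; everywhere the shared vasomotion
#' sinusoids, the linear drift and i.i.d. Gaussian noise are added as
#' fractional modulations of the baseline. Optional integer-pixel global
#' translations emulate frame-to-frame motion. The same configuration and
#' seed always produce a bit-identical stack.
#'
#' @param config a [SimulationConfig-class].
#' @return list with elements `sequence` (a [ReflectanceSequence-class]) and
#'   `truth` (a [SimulationTruth-class]).
#' @examples
#' cfg <- simulationConfig(gridRows = 24, gridCols = 24,
#'   paradigm = stimulusParadigm(cycles = 3), seed = 7)
#' sim <- simulateSequence(cfg)
#' sim$sequence
#' @export
simulateSequence <- function(config) {
  validObject(config)
  truth <- buildTruthMasks(config)
  p <- config@paradigm
  n <- totalFrames(p)
  R <- config@gridRows; C <- config@gridCols
  npix <- R * C
  dt <- 1 / p@frameRate
  t <- (seq_len(n) - 1L) * dt

  r <- responseWaveform(p, config@responseDelay, config@responseTau)

  vaso <- numeric(n)
  vm <- config@vasomotion
  for (i in seq_len(nrow(vm)))
    vaso <- vaso + vm$amplitude[i] * sin(2 * pi * vm$frequency[i] * t +
                                           vm$phase[i])
  drift <- config@driftSlope * t / 60

  set.seed(as.integer(config@seed))
  noise <- if (config@noiseSd > 0)
    matrix(stats::rnorm(n * npix, sd = config@noiseSd), n, npix)
  else matrix(0, n, npix)

  ampVec <- as.vector(truth@amplitudeMap)
  modul <- 1 + outer(r, ampVec) + vaso + drift + noise
  stack <- config@baselineLevel * modul
  arr <- array(stack, dim = c(n, R, C))

  if (config@motionMaxShift > 0) {
    m <- as.integer(config@motionMaxShift)
    dy <- sample.int(2L * m + 1L, n, replace = TRUE) - m - 1L
    dx <- sample.int(2L * m + 1L, n, replace = TRUE) - m - 1L
    for (i in seq_len(n))
      if (dy[i] != 0L || dx[i] != 0L)
        arr[i, , ] <- shiftFrame(arr[i, , ], dy[i], dx[i])
  }

  seq <- reflectanceSequence(arr, frameInterval = dt,
                             channelOrigin = "synthetic",
                             processingLog = sprintf("simulated(seed=%d)",
                                                     as.integer(config@seed)))
  list(sequence = seq, truth = truth)
}

#' Simulate an RGB camera recording
#'
#' Emulates acquisition with a microscope-integrated RGB camera: the green
#' channel carries the simulated reflectance of [simulateSequence()]
#' (optionally quantized to 8 bit per channel, as such cameras digitize),
#' while the red and blue channels carry the baseline plus independent noise
#' only. Quantization maps the range `[0, 2 * baselineLevel]` linearly onto
#' `0..255`, so the baseline sits at mid-range.
#'
#' @param config a [SimulationConfig-class].
#' @param quantize logical; if `FALSE` the channels are returned as
#'   unquantized doubles (useful for exact-equality checks).
#' @return list with `rgb` (time x rows x cols x 3 array), `truth`
#'   (a [SimulationTruth-class]) and `frameInterval` (seconds).
#' @seealso [extractGreenChannel()], [dequantize8bit()]
#' @export
simulateRgbSequence <- function(config, quantize = TRUE) {
  sim <- simulateSequence(config)
  green <- frames(sim$sequence)
  n <- dim(green)[1L]; R <- dim(green)[2L]; C <- dim(green)[3L]
  b <- config@baselineLevel
  mkNoise <- function() {
    if (config@noiseSd > 0)
      array(b * (1 + stats::rnorm(n * R * C, sd = config@noiseSd)),
            dim = c(n, R, C))
    else array(b, dim = c(n, R, C))
  }
  ## RNG state continues from simulateSequence, keeping the green channel
  ## identical between the grayscale and RGB simulations
  red <- mkNoise(); blue <- mkNoise()
  rgb <- array(0, dim = c(n, R, C, 3L))
  rgb[, , , 1L] <- red; rgb[, , , 2L] <- green; rgb[, , , 3L] <- blue
  if (quantize) {
    rgb <- round(rgb / (2 * b) * 255)
    rgb[rgb < 0] <- 0; rgb[rgb > 255] <- 255
  }
  list(rgb = rgb, truth = sim$truth,
       frameInterval = frameInterval(sim$sequence))
}

#' Undo the 8-bit quantization of a simulated RGB channel
#'
#' Inverse of the linear 8-bit mapping used by [simulateRgbSequence()]:
#' digital value `v` maps back to reflectance `v / 255 * 2 * baselineLevel`.
#'
#' @param x array of 8-bit digital values.
#' @param baselineLevel the baseline used at simulation time.
#' @return array of reflectance values.
#' @export
dequantize8bit <- function(x, baselineLevel = 1) {
  x / 255 * 2 * baselineLevel
}

#' Ground-truth masks as a region mask set
#'
#' Repackages a [SimulationTruth-class] as the [RegionMaskSet-class] the
#' comparison stage consumes, with the injected activation playing the role
#' of the reference mask.
#'
#' @param truth a [SimulationTruth-class].
#' @return A [RegionMaskSet-class].
#' @export
asRegionMaskSet <- function(truth) {
  stopifnot(is(truth, "SimulationTruth"))
  regionMaskSet(trepanation = truth@trepanationMask, psc = truth@pscMask,
                referenceActivation = truth@activationMask)
}
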