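#' Pixelwise one-sided power spectrum
#'
#' Computes, for every pixel, the discrete Fourier power spectrum of its
#' temporal trace. With `N` frames and DFT coefficients `X_k`, the reported
#' power at bin `k` is `|X_k|^2 / N`, doubled for the interior bins
#' `k = 1 .. ceil(N/2) - 1` (and, for odd `N`, the last bin) so that the
#' one-sided sum preserves total power. Under this normalization the sum of
#' all non-DC one-sided power equals the sum of squared deviations from the
#' trace mean (`N` times the population variance). The DC bin (`k = 0`,
#' mean brightness) is reported but flagged; it never enters the vasomotion
#' band.
#'
#' @param seq a [ReflectanceSequence-class] with at least 4 frames.
#' @param window `"none"` (default) or `"hann"`. The default record holds an
#'   integer number of stimulation cycles, so the stimulation component is
#'   bin-aligned and needs no window; a Hann window trades that exactness
#'   for reduced leakage of non-bin-aligned components and smears each line
#'   over neighbouring bins.
#' @return list with elements `freq` (Hz, one value per bin), `power`
#'   (bins x rows x cols array), `dcBin` (the index of the flagged DC bin,
#'   always 1) and `nFrames`.
#' @examples
#' s <- reflectanceSequence(array(sin(2 * pi * (0:63) / 16), c(64, 1, 1)),
#'                          frameInterval = 0.5)
#' sp <- powerSpectrumPixelwise(s)
#' sp$freq[which.max(sp$power[, 1, 1][-1]) + 1]  # 1/8 Hz line
#' @export
powerSpectrumPixelwise <- function(seq, window = c("none", "hann")) {
  stopifnot(is(seq, "ReflectanceSequence"))
  window <- match.arg(window)
  arr <- frames(seq)
  d <- dim(arr)
  n <- d[1L]
  if (n < 4L) stop("spectral analysis needs at least 4 frames")
  x <- matrix(arr, n, d[2L] * d[3L])
  if (window == "hann") {
    w <- 0.5 - 0.5 * cos(2 * pi * (seq_len(n) - 1L) / n)
    x <- x * w
  }
  nb <- floor(n / 2) + 1L
  X <- stats::mvfft(x)[seq_len(nb), , drop = FALSE]
  pw <- (Mod(X)^2) / n
  dbl <- if (n %% 2 == 0) seq(2L, nb - 1L) else seq(2L, nb)
  pw[dbl, ] <- 2 * pw[dbl, ]
  list(freq = (seq_len(nb) - 1L) / (n * frameInterval(seq)),
       power = array(pw, dim = c(nb, d[2L], d[3L])),
       dcBin = 1L, nFrames = n)
}

## internal: nearest frame counts placing f_stim exactly on a DFT bin
nearestBinAlignedLengths <- function(fStim, dt, n) {
  k <- fStim * n * dt
  lo <- floor(k); hi <- ceiling(k)
  sort(unique(round(c(lo, hi, max(1, lo), hi + 1) / (fStim * dt))))
}

#' Compute the spectral activity map
#'
#' The core mapping statistic: per pixel, the one-sided power at the
#' stimulation frequency (`P_s`) divided by the summed one-sided power over
#' the very-low-frequency vasomotion band (`P_VLF`, frequencies strictly
#' between 0 and `vlfMax`). The ratio expresses stimulation-locked power
#' relative to the vasomotor background and is invariant to global gain.
#'
#' The DC bin is always excluded from the VLF sum. Because the stimulation
#' frequency (1/60 Hz for 30 s + 30 s blocks) itself lies inside the VLF
#' band, the stimulation bin plus a one-bin guard on either side is excluded
#' from the denominator by default — otherwise a true activation would
#' suppress its own ratio.
#'
#' @param seq a [ReflectanceSequence-class].
#' @param paradigm a [StimulusParadigm-class]; its stimulation frequency
#'   must fall exactly on a DFT bin of the record (guaranteed when the
#'   record holds a whole number of cycles).
#' @param vlfMax upper VLF band edge in Hz; the band is the half-open
#'   interval (0, `vlfMax`), so a bin exactly at `vlfMax` is excluded.
#' @param excludeStimBinFromVlf drop the stimulation bin (with guard) from
#'   the VLF sum (default `TRUE`).
#' @param guardBins half-width of the stimulation-bin exclusion, in bins.
#' @param window passed to [powerSpectrumPixelwise()].
#' @param measure `"power"` (default) uses one-sided power `|X|^2`-based
#'   values; `"amplitude"` uses their square roots for both numerator and
#'   band sum.
#' @return An [ActivityMap-class]. Pixels with zero band power get ratio 0
#'   and are counted in the `zeroDenominatorCount` diagnostic.
#' @examples
#' cfg <- simulationConfig(gridRows = 16, gridCols = 16,
#'   paradigm = stimulusParadigm(cycles = 3), seed = 2)
#' sim <- simulateSequence(cfg)
#' am <- computeActivityMap(detrendPixelwise(sim$sequence), cfg@paradigm)
#' am
#' @export
computeActivityMap <- function(seq, paradigm, vlfMax = 0.04,
                               excludeStimBinFromVlf = TRUE,
                               guardBins = 1L,
                               window = c("none", "hann"),
                               measure = c("power", "amplitude")) {
  stopifnot(is(seq, "ReflectanceSequence"), is(paradigm, "StimulusParadigm"))
  measure <- match.arg(measure)
  fStim <- stimFrequency(paradigm)
  if (fStim >= vlfMax)
    warning("stimulation frequency ", signif(fStim, 4),
            " Hz lies at or above the VLF band edge ", vlfMax, " Hz")
  n <- nFrames(seq)
  dt <- frameInterval(seq)
  k0 <- fStim * n * dt
  if (abs(k0 - round(k0)) > 1e-9) {
    near <- nearestBinAlignedLengths(fStim, dt, n)
    stop(sprintf(
      "stimulation frequency %.6g Hz does not fall on a DFT bin of a %d-frame record; nearest bin-aligned record lengths: %s frames",
      fStim, n, paste(near, collapse = ", ")))
  }
  k0 <- as.integer(round(k0))
  sp <- powerSpectrumPixelwise(seq, window = match.arg(window))
  nb <- length(sp$freq)
  if (k0 < 1L || k0 > nb - 1L)
    stop("stimulation bin ", k0, " outside the resolvable spectrum")
  pw <- matrix(sp$power, nb, prod(dim(sp$power)[2:3]))
  if (measure == "amplitude") pw <- sqrt(pw)

  bins0 <- seq_len(nb) - 1L                    # 0-based bin indices
  inBand <- sp$freq > 0 & sp$freq < vlfMax
  excluded <- 0L                               # DC, always
  if (excludeStimBinFromVlf) {
    guard <- seq.int(k0 - guardBins, k0 + guardBins)
    excluded <- c(excluded, guard[guard >= 0 & guard <= nb - 1L])
  }
  vlfBins <- bins0[inBand & !(bins0 %in% excluded)]
  if (!length(vlfBins))
    warning("no frequency bins remain in the VLF band; ",
            "denominator is zero everywhere")

  d <- dim(sp$power)[2:3]
  pS <- matrix(pw[k0 + 1L, ], d[1L], d[2L])
  pVLF <- if (length(vlfBins))
    matrix(colSums(pw[vlfBins + 1L, , drop = FALSE]), d[1L], d[2L])
  else matrix(0, d[1L], d[2L])
  zero <- pVLF <= 0
  ratio <- matrix(0, d[1L], d[2L])
  ratio[!zero] <- pS[!zero] / pVLF[!zero]

  new("ActivityMap", ratio = ratio, pS = pS, pVLF = pVLF, fStim = fStim,
      vlfBand = c(0, vlfMax), excludedBins = as.integer(sort(unique(excluded))),
      zeroDenominatorCount = as.integer(sum(zero)),
      freqResolution = 1 / (n * dt))
}
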