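#' Extract the green channel of an RGB recording
#'
#' RGB camera recordings are reduced to the green channel before spectral
#' mapping: in the green band, absorption by both oxy- and deoxyhemoglobin
#' is strong, so reflectance there tracks cerebral blood volume much like a
#' 568 nm filtered acquisition.
#'
#' @param rgbStack a time x rows x cols x 3 numeric array, or the list
#'   returned by [simulateRgbSequence()].
#' @param frameInterval seconds between frames (ignored when `rgbStack`
#'   carries its own).
#' @return A [ReflectanceSequence-class] with `channelOrigin = "rgb_green"`.
#' @export
extractGreenChannel <- function(rgbStack, frameInterval = 0.5) {
  if (is.list(rgbStack) && !is.null(rgbStack$rgb)) {
    if (!is.null(rgbStack$frameInterval))
      frameInterval <- rgbStack$frameInterval
    rgbStack <- rgbStack$rgb
  }
  d <- dim(rgbStack)
  if (length(d) != 4L)
    stop("expected a 4-D time x rows x cols x channels array")
  if (d[4L] != 3L)
    stop("expected exactly 3 channels, got ", d[4L])
  green <- array(rgbStack[, , , 2L], dim = d[1:3])
  reflectanceSequence(green, frameInterval = frameInterval,
                      channelOrigin = "rgb_green",
                      processingLog = "extract_green_channel")
}

## internal: FFT-based circular cross-correlation, returning the shift to
## APPLY to `frame` so it aligns with `ref` (the negated displacement),
## restricted to |dy|,|dx| <= maxShift; ties resolved toward the smallest
## shift (so constant frames give (0,0))
estimateShift <- function(ref, frame, maxShift) {
  R <- nrow(ref); C <- ncol(ref)
  a <- ref - mean(ref); b <- frame - mean(frame)
  cc <- Re(stats::fft(stats::fft(a) * Conj(stats::fft(b)), inverse = TRUE))
  toSigned <- function(i, n) ifelse(i > n / 2, i - n, i)
  dys <- toSigned(seq_len(R) - 1L, R)
  dxs <- toSigned(seq_len(C) - 1L, C)
  okR <- which(abs(dys) <= maxShift)
  okC <- which(abs(dxs) <= maxShift)
  cand <- expand.grid(iy = okR, ix = okC)
  cand$dy <- dys[cand$iy]; cand$dx <- dxs[cand$ix]
  cand <- cand[order(abs(cand$dy) + abs(cand$dx), abs(cand$dy),
                     cand$dy, cand$dx), ]
  vals <- cc[cbind(cand$iy, cand$ix)]
  best <- max(vals)
  tol <- 1e-9 * max(1, abs(best))
  hit <- which(vals >= best - tol)[1L]
  c(cand$dy[hit], cand$dx[hit])
}

#' Compensate global frame-to-frame motion
#'
#' Aligns every frame to a reference frame by the integer-pixel translation
#' that maximizes their cross-correlation. Border pixels exposed by the
#' translation are filled with the frame's median. This rigid scheme
#' handles the translational component of intraoperative motion (pulsation,
#' microscope drift); it is an extension point, not a deformable
#' registration.
#'
#' @param seq a [ReflectanceSequence-class] with at least 2 frames.
#' @param referenceIndex 1-based index of the reference frame (default 1).
#' @param maxShift search radius in pixels (default one quarter of the
#'   shorter image side).
#' @return The aligned [ReflectanceSequence-class]; the applied shifts are
#'   recorded in the processing log. Applying the operation twice equals
#'   applying it once.
#' @export
compensateMotion <- function(seq, referenceIndex = 1L, maxShift = NULL) {
  stopifnot(is(seq, "ReflectanceSequence"))
  arr <- frames(seq)
  n <- dim(arr)[1L]
  if (n < 2L) stop("motion compensation needs at least 2 frames")
  if (referenceIndex < 1L || referenceIndex > n)
    stop("reference index ", referenceIndex, " out of range 1..", n)
  if (is.null(maxShift))
    maxShift <- max(1L, floor(min(dim(arr)[2:3]) / 4))
  ref <- arr[referenceIndex, , ]
  shifts <- matrix(0L, n, 2L)
  for (i in seq_len(n)) {
    if (i == referenceIndex) next
    s <- estimateShift(ref, arr[i, , ], maxShift)
    shifts[i, ] <- s
    if (any(s != 0L)) arr[i, , ] <- shiftFrame(arr[i, , ], s[1L], s[2L])
  }
  moved <- which(rowSums(abs(shifts)) > 0)
  desc <- if (length(moved))
    paste0(sprintf("%d:(%d,%d)", moved, shifts[moved, 1L],
                   shifts[moved, 2L]), collapse = " ")
  else "none"
  out <- reflectanceSequence(arr, frameInterval = frameInterval(seq),
                             channelOrigin = channelOrigin(seq),
                             processingLog = processingLog(seq))
  logStep(out, sprintf("compensate_motion(reference=%d, shifts: %s)",
                       referenceIndex, desc))
}

#' Remove the per-pixel linear trend
#'
#' Subtracts, pixel by pixel, the least-squares straight line fitted to the
#' temporal trace. This suppresses slow illumination or physiological drift
#' that would otherwise leak into the very-low-frequency band of the power
#' spectrum. Output traces have zero temporal mean and zero linear slope.
#'
#' @param seq a [ReflectanceSequence-class] with at least 3 frames.
#' @return The detrended [ReflectanceSequence-class].
#' @export
detrendPixelwise <- function(seq) {
  stopifnot(is(seq, "ReflectanceSequence"))
  arr <- frames(seq)
  d <- dim(arr)
  n <- d[1L]
  if (n < 3L) stop("detrending needs at least 3 frames")
  x <- matrix(arr, n, d[2L] * d[3L])
  tc <- seq_len(n) - (n + 1) / 2
  xc <- sweep(x, 2L, colMeans(x))
  slope <- crossprod(tc, xc) / sum(tc * tc)
  out <- xc - tcrossprod(tc, as.vector(slope))
  res <- reflectanceSequence(array(out, dim = d),
                             frameInterval = frameInterval(seq),
                             channelOrigin = channelOrigin(seq),
                             processingLog = processingLog(seq))
  logStep(res, "detrend_pixelwise")
}
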