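## File conventions used by every writer: images are (row, col) with the
## origin at the top-left; stacks put time first. Masks are 8-bit
## single-page PNG or TIFF with 0 = background and 255 = foreground; any
## nonzero pixel reads back as TRUE. Stacks are multi-page 32-bit float
## TIFF, one page per frame, linearly mapped into [0, 1] with the affine
## mapping (offset, scale) recorded in a JSON sidecar next to the file.

#' Write / read a binary mask image
#'
#' Masks are stored as single-page 8-bit images (PNG or TIFF by file
#' extension), 0 for background and 255 for foreground. On reading, any
#' nonzero pixel is foreground; multi-channel images are reduced to their
#' first channel.
#'
#' @param mask logical matrix.
#' @param path file path ending in `.png`, `.tif` or `.tiff`.
#' @return `writeMask` returns `path` invisibly; `readMask` returns a
#'   logical matrix.
#' @export
writeMask <- function(mask, path) {
  stopifnot(is.matrix(mask))
  img <- matrix(as.numeric(mask != 0), nrow(mask), ncol(mask))
  ext <- tolower(tools::file_ext(path))
  if (ext == "png") png::writePNG(img, path)
  else if (ext %in% c("tif", "tiff"))
    tiff::writeTIFF(img, path, bits.per.sample = 8L, compression = "none")
  else stop("unsupported mask format: .", ext)
  invisible(path)
}

#' @rdname writeMask
#' @export
readMask <- function(path) {
  ext <- tolower(tools::file_ext(path))
  img <- if (ext == "png") png::readPNG(path)
  else if (ext %in% c("tif", "tiff")) tiff::readTIFF(path)
  else stop("unsupported mask format: .", ext)
  if (length(dim(img)) == 3L) img <- img[, , 1L]
  img != 0
}

#' Write / read a reflectance stack as multi-page TIFF
#'
#' One 32-bit float page per frame. Because the TIFF writer stores values
#' in [0, 1], frames are mapped linearly into that range and the affine
#' mapping, the frame interval, the channel origin and the processing log
#' are recorded in a JSON sidecar (`<path>.json`); reading restores the
#' original values at 32-bit float precision.
#'
#' @param seq a [ReflectanceSequence-class].
#' @param path file path ending in `.tif` or `.tiff`.
#' @return `writeStack` returns `path` invisibly; `readStack` returns a
#'   [ReflectanceSequence-class].
#' @export
writeStack <- function(seq, path) {
  stopifnot(is(seq, "ReflectanceSequence"))
  arr <- frames(seq)
  lo <- min(arr); hi <- max(arr)
  scale <- if (hi > lo) hi - lo else 1
  n <- dim(arr)[1L]
  pages <- lapply(seq_len(n), function(i) (arr[i, , ] - lo) / scale)
  tiff::writeTIFF(pages, path, bits.per.sample = 32L, compression = "none")
  meta <- list(offset = lo, scale = scale,
               frameInterval = frameInterval(seq),
               channelOrigin = channelOrigin(seq),
               processingLog = as.list(processingLog(seq)))
  jsonlite::write_json(meta, paste0(path, ".json"), auto_unbox = TRUE,
                       digits = NA)
  invisible(path)
}

#' @rdname writeStack
#' @param frameInterval fallback frame interval in seconds, used only when
#'   the sidecar is missing.
#' @export
readStack <- function(path, frameInterval = NULL) {
  pages <- tiff::readTIFF(path, all = TRUE)
  if (!is.list(pages)) pages <- list(pages)
  side <- paste0(path, ".json")
  meta <- if (file.exists(side)) jsonlite::read_json(side, simplifyVector = TRUE)
  else list(offset = 0, scale = 1,
            frameInterval = frameInterval,
            channelOrigin = "filtered_568nm", processingLog = character())
  if (is.null(meta$frameInterval))
    stop("no frame interval: sidecar missing and none supplied")
  d <- dim(pages[[1L]])
  arr <- array(0, dim = c(length(pages), d[1L], d[2L]))
  for (i in seq_along(pages))
    arr[i, , ] <- pages[[i]] * meta$scale + meta$offset
  reflectanceSequence(arr, frameInterval = meta$frameInterval,
                      channelOrigin = meta$channelOrigin,
                      processingLog = as.character(unlist(meta$processingLog)))
}

## internal: one float map as single-page TIFF + sidecar (same affine
## convention as writeStack)
writeFloatMap <- function(m, path) {
  lo <- min(m); hi <- max(m)
  scale <- if (hi > lo) hi - lo else 1
  tiff::writeTIFF((m - lo) / scale, path, bits.per.sample = 32L,
                  compression = "none")
  jsonlite::write_json(list(offset = lo, scale = scale),
                       paste0(path, ".json"), auto_unbox = TRUE, digits = NA)
  invisible(path)
}

readFloatMap <- function(path) {
  m <- tiff::readTIFF(path)
  meta <- jsonlite::read_json(paste0(path, ".json"), simplifyVector = TRUE)
  m * meta$scale + meta$offset
}

#' Write an activity map bundle
#'
#' Writes the ratio map, the stimulation-power and VLF-power constituents
#' as 32-bit float TIFFs (with affine sidecars) plus a JSON metadata file
#' holding the stimulation frequency, the VLF band, the excluded bins and
#' the zero-denominator pixel count.
#'
#' @param map an [ActivityMap-class].
#' @param dir output directory (created if missing).
#' @return invisibly, the paths written.
#' @export
writeActivityMap <- function(map, dir) {
  stopifnot(is(map, "ActivityMap"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  paths <- c(
    ratio = file.path(dir, "ratio.tif"),
    p_s = file.path(dir, "p_s.tif"),
    p_vlf = file.path(dir, "p_vlf.tif"),
    meta = file.path(dir, "activity_map.json"))
  writeFloatMap(map@ratio, paths["ratio"])
  writeFloatMap(map@pS, paths["p_s"])
  writeFloatMap(map@pVLF, paths["p_vlf"])
  jsonlite::write_json(list(
    f_stim = map@fStim, vlf_band = map@vlfBand,
    excluded_bins = map@excludedBins,
    zero_denominator_pixels = map@zeroDenominatorCount,
    freq_resolution = map@freqResolution),
    paths["meta"], auto_unbox = TRUE, digits = NA)
  invisible(paths)
}

#' Write a comparison report as JSON
#'
#' @param report a [ComparisonReport-class].
#' @param path output file path.
#' @param extra optional named list merged into the JSON (e.g. the
#'   segmentation threshold).
#' @return `path`, invisibly.
#' @export
writeReport <- function(report, path, extra = list()) {
  stopifnot(is(report, "ComparisonReport"))
  x <- c(list(
    dice = list(activation = report@diceActivation,
                hull = report@diceHull,
                full = report@diceFull),
    region_stats = report@regionStats,
    notes = as.list(report@notes)), extra)
  jsonlite::write_json(x, path, auto_unbox = TRUE, digits = NA,
                       dataframe = "rows")
  invisible(path)
}
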