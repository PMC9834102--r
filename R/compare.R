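#' DICE similarity coefficient of two binary masks
#'
#' `2 |A intersect B| / (|A| + |B|)`. When both masks are empty the
#' coefficient is mathematically undefined; this implementation returns 0
#' with a warning — a silent 1 would fabricate agreement.
#'
#' @param a,b logical matrices on the same grid.
#' @return number in [0, 1].
#' @examples
#' m <- matrix(FALSE, 4, 4); n <- m
#' m[1:2, 1:2] <- TRUE; n[2:3, 1:2] <- TRUE
#' dice(m, n)  # |A| = |B| = 4, overlap 2 -> 0.5
#' @export
dice <- function(a, b) {
  stopifnot(is.matrix(a), is.matrix(b))
  if (!identical(dim(a), dim(b)))
    stop("masks differ in shape: ", paste(dim(a), collapse = "x"), " vs ",
         paste(dim(b), collapse = "x"))
  a <- a != 0; b <- b != 0
  na <- sum(a); nb <- sum(b)
  if (na + nb == 0L) {
    warning("both masks are empty; DICE undefined, returning 0")
    return(0)
  }
  2 * sum(a & b) / (na + nb)
}

#' The three DICE variants against a reference mask
#'
#' Compares a segmentation with a reference activation (e.g. fMRI-derived)
#' three ways: segmented activation vs reference, convex hull of the
#' activation vs reference, and the complete thresholded map vs reference.
#' The reference is clipped to the trepanation first, since only the
#' trepanned area is visible to the camera.
#'
#' @param seg an [ActivationSegmentation-class].
#' @param reference logical matrix.
#' @param trepanation logical matrix.
#' @return named numeric vector `c(activation=, hull=, full=)`.
#' @export
diceTriplet <- function(seg, reference, trepanation) {
  stopifnot(is(seg, "ActivationSegmentation"))
  reference <- (reference != 0) & (trepanation != 0)
  c(activation = dice(seg@activation, reference),
    hull = dice(seg@hull, reference),
    full = dice(seg@thresholdedMap, reference))
}

## internal: quartiles of a region's values; linear interpolation between
## order statistics (stats::quantile type 7), the configurable default
regionQuartiles <- function(v, quantileType = 7) {
  if (!length(v))
    return(c(median = NA_real_, q1 = NA_real_, q3 = NA_real_))
  q <- stats::quantile(v, probs = c(0.25, 0.5, 0.75), type = quantileType,
                       names = FALSE)
  c(median = q[2L], q1 = q[1L], q3 = q[3L])
}

#' Region-restricted statistics of the activity map
#'
#' Splits the trepanation into three disjoint regions — the reference
#' activation, the PSC outside the reference, and the surrounding area
#' (trepanation outside the PSC) — and reports median, first and third
#' quartile and pixel count of the raw ratio values in each. Masks are
#' restricted to the expected nesting first (PSC to the trepanation,
#' reference to the PSC), so the three regions always partition the
#' trepanation.
#'
#' @param map an [ActivityMap-class] or numeric matrix.
#' @param masks a [RegionMaskSet-class] with PSC and reference masks
#'   present.
#' @param quantileType quantile convention as in [stats::quantile()]
#'   (default 7, linear interpolation).
#' @return data frame with columns `region`, `n`, `median`, `q1`, `q3`;
#'   empty regions get `n = 0` and `NA` statistics.
#' @export
regionStatistics <- function(map, masks, quantileType = 7) {
  m <- if (is(map, "ActivityMap")) ratioMap(map) else map
  stopifnot(is(masks, "RegionMaskSet"))
  if (is.null(masks@psc) || is.null(masks@referenceActivation))
    stop("region statistics need both PSC and reference-activation masks")
  trep <- masks@trepanation
  stopifnot(identical(dim(m), dim(trep)))
  psc <- masks@psc & trep
  ref <- masks@referenceActivation & psc
  regions <- list(
    reference_activation = ref,
    psc_minus_reference = psc & !ref,
    surrounding = trep & !psc
  )
  out <- do.call(rbind, lapply(names(regions), function(nm) {
    v <- m[regions[[nm]]]
    q <- regionQuartiles(v, quantileType)
    data.frame(region = nm, n = length(v), median = q[["median"]],
               q1 = q[["q1"]], q3 = q[["q3"]])
  }))
  row.names(out) <- NULL
  out
}

#' Build a full comparison report
#'
#' Convenience wrapper combining [diceTriplet()] and [regionStatistics()]
#' into a [ComparisonReport-class].
#'
#' @param map an [ActivityMap-class] or numeric matrix.
#' @param seg an [ActivationSegmentation-class].
#' @param masks a [RegionMaskSet-class]; its `referenceActivation` is the
#'   comparison reference.
#' @param quantileType passed to [regionStatistics()].
#' @return A [ComparisonReport-class].
#' @export
compareToReference <- function(map, seg, masks, quantileType = 7) {
  stopifnot(is(masks, "RegionMaskSet"))
  if (is.null(masks@referenceActivation))
    stop("comparison needs a reference-activation mask")
  notes <- character()
  triplet <- withCallingHandlers(
    diceTriplet(seg, masks@referenceActivation, masks@trepanation),
    warning = function(w) {
      notes <<- c(notes, conditionMessage(w))
      invokeRestart("muffleWarning")
    })
  rs <- if (!is.null(masks@psc))
    regionStatistics(map, masks, quantileType)
  else
    data.frame(region = character(), n = integer(), median = numeric(),
               q1 = numeric(), q3 = numeric())
  new("ComparisonReport",
      diceActivation = unname(triplet["activation"]),
      diceHull = unname(triplet["hull"]),
      diceFull = unname(triplet["full"]),
      regionStats = rs, notes = notes)
}

#' Compose segmented activations of several stimulation sites
#'
#' Assembles the activation masks of multiple stimulation sites (different
#' body parts) into one integer label map, the topographic overlay along
#' the sensory cortex. Pixels claimed by several sites are assigned to the
#' earliest-listed site; the untouched per-site masks are kept so no
#' information is lost, and a pairwise site-overlap DICE matrix is reported
#' alongside.
#'
#' @param segmentations list of [ActivationSegmentation-class] objects (or
#'   logical matrices), one per site, all on one grid.
#' @param siteNames character vector of unique site names, same length.
#' @return A [TopographicMap-class].
#' @export
composeTopography <- function(segmentations, siteNames) {
  if (length(segmentations) != length(siteNames))
    stop("one name per site required")
  if (anyDuplicated(siteNames))
    stop("duplicated site names: ",
         paste(unique(siteNames[duplicated(siteNames)]), collapse = ", "))
  masks <- lapply(segmentations, function(s) {
    m <- if (is(s, "ActivationSegmentation")) s@activation else s
    stopifnot(is.matrix(m))
    m != 0
  })
  d <- dim(masks[[1L]])
  for (m in masks) stopifnot(identical(dim(m), d))
  n <- length(masks)
  lab <- matrix(0L, d[1L], d[2L])
  for (i in rev(seq_len(n))) lab[masks[[i]]] <- i  # earlier sites overwrite
  ov <- diag(1, n)
  dimnames(ov) <- list(siteNames, siteNames)
  if (n > 1L)
    for (i in seq_len(n - 1L)) for (j in seq.int(i + 1L, n)) {
      dij <- suppressWarnings(dice(masks[[i]], masks[[j]]))
      ov[i, j] <- ov[j, i] <- dij
    }
  names(masks) <- siteNames
  new("TopographicMap", labelMap = lab, siteNames = siteNames,
      overlapPolicy = "overlapping pixels assigned to the earliest-listed site",
      overlapDice = ov, siteMasks = masks)
}

#' Centroids of the per-site activations of a topographic map
#'
#' @param topo a [TopographicMap-class].
#' @return data frame with columns `site`, `row`, `col` (centroids of the
#'   original per-site masks; `NA` for empty sites).
#' @export
siteCentroids <- function(topo) {
  stopifnot(is(topo, "TopographicMap"))
  out <- do.call(rbind, lapply(topo@siteNames, function(nm) {
    idx <- which(topo@siteMasks[[nm]], arr.ind = TRUE)
    if (!nrow(idx))
      data.frame(site = nm, row = NA_real_, col = NA_real_)
    else
      data.frame(site = nm, row = mean(idx[, 1L]), col = mean(idx[, 2L]))
  }))
  row.names(out) <- NULL
  out
}
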