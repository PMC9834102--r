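#' Label connected components of a binary mask
#'
#' Flood-fill labelling with 8-connectivity (default; diagonal neighbours
#' touch) or 4-connectivity. Labels are positive integers; background is 0.
#'
#' @param mask logical matrix.
#' @param connectivity 8 (default) or 4.
#' @return integer matrix of component labels.
#' @export
labelComponents <- function(mask, connectivity = 8) {
  stopifnot(is.matrix(mask), connectivity %in% c(4, 8))
  R <- nrow(mask); C <- ncol(mask)
  mask <- mask != 0
  lab <- matrix(0L, R, C)
  off <- if (connectivity == 8)
    cbind(c(-1L, -1L, -1L, 0L, 0L, 1L, 1L, 1L),
          c(-1L, 0L, 1L, -1L, 1L, -1L, 0L, 1L))
  else
    cbind(c(-1L, 1L, 0L, 0L), c(0L, 0L, -1L, 1L))
  cur <- 0L
  for (start in which(mask)) {
    if (lab[start] != 0L) next
    cur <- cur + 1L
    lab[start] <- cur
    frontier <- start
    while (length(frontier)) {
      qr <- ((frontier - 1L) %% R) + 1L
      qc <- ((frontier - 1L) %/% R) + 1L
      nxt <- integer()
      for (k in seq_len(nrow(off))) {
        nr <- qr + off[k, 1L]; nc <- qc + off[k, 2L]
        ok <- nr >= 1L & nr <= R & nc >= 1L & nc <= C
        ni <- (nc[ok] - 1L) * R + nr[ok]
        ni <- ni[mask[ni] & lab[ni] == 0L]
        if (length(ni)) {
          lab[ni] <- cur
          nxt <- c(nxt, ni)
        }
      }
      frontier <- unique(nxt)
    }
  }
  lab
}

## internal: summary table of labelled components; firstIndex is the
## smallest row-major index (origin top-left, rows scanned first) — the
## deterministic tie-break key for equal sizes
componentSummary <- function(lab) {
  labs <- sort(unique(lab[lab > 0L]))
  if (!length(labs))
    return(data.frame(label = integer(), size = integer(),
                      centroidRow = numeric(), centroidCol = numeric(),
                      firstIndex = integer()))
  R <- nrow(lab); C <- ncol(lab)
  idx <- which(lab > 0L)
  l <- lab[idx]
  r <- ((idx - 1L) %% R) + 1L
  c <- ((idx - 1L) %/% R) + 1L
  rowMajor <- (r - 1L) * C + c
  data.frame(
    label = labs,
    size = as.integer(tapply(l, l, length)),
    centroidRow = as.numeric(tapply(r, l, mean)),
    centroidCol = as.numeric(tapply(c, l, mean)),
    firstIndex = as.integer(tapply(rowMajor, l, min)),
    row.names = NULL
  )
}

#' Threshold an activity map within the trepanation
#'
#' Computes the segmentation threshold `z_thresh = mean + k_sd * SD` of the
#' activity-map values over the trepanation pixels (population SD) and
#' returns the binary mask of trepanation pixels strictly above it. Strict
#' inequality means a constant map yields an empty mask rather than a full
#' one. Because the rule is affine-equivariant, rescaling the map by any
#' positive affine transform leaves the mask unchanged.
#'
#' @param map an [ActivityMap-class] or a numeric matrix.
#' @param trepanation logical matrix, non-empty.
#' @param kSd SD multiplier (default 1; awake measurements may need a
#'   higher value for a well-delineated activation).
#' @return list with `zThresh` (the threshold) and `mask` (logical matrix).
#' @export
thresholdActivity <- function(map, trepanation, kSd = 1) {
  m <- if (is(map, "ActivityMap")) ratioMap(map) else map
  stopifnot(is.matrix(m), is.matrix(trepanation),
            identical(dim(m), dim(trepanation)))
  trepanation <- trepanation != 0
  if (!any(trepanation)) stop("trepanation mask is empty")
  v <- m[trepanation]
  mu <- mean(v)
  sdPop <- sqrt(mean((v - mu)^2))
  z <- mu + kSd * sdPop
  list(zThresh = z, mask = (m > z) & trepanation)
}

#' Remove small connected components
#'
#' Area opening: every connected component with fewer than `minSize` pixels
#' is removed; components with at least `minSize` pixels are kept intact.
#'
#' @param mask logical matrix.
#' @param minSize minimum pixel count to survive (default 10, i.e.
#'   components smaller than 10 pixels are removed).
#' @param connectivity 8 (default) or 4.
#' @return logical matrix.
#' @export
removeSmallComponents <- function(mask, minSize = 10, connectivity = 8) {
  mask <- mask != 0
  if (!any(mask)) return(mask)
  lab <- labelComponents(mask, connectivity)
  sizes <- tabulate(lab[lab > 0L])
  keep <- which(sizes >= minSize)
  out <- matrix(lab %in% keep, nrow(mask), ncol(mask))
  out
}

#' Select the largest connected components
#'
#' Keeps the union of the `k` largest components by pixel count (all of
#' them when fewer exist). Ties in size are broken deterministically by the
#' smallest row-major pixel index.
#'
#' @param mask logical matrix.
#' @param k number of components to keep (default 3).
#' @param connectivity 8 (default) or 4.
#' @return list with `mask` (the union) and `components` (the full
#'   component table with a logical `selected` column).
#' @export
selectLargestComponents <- function(mask, k = 3, connectivity = 8) {
  mask <- mask != 0
  lab <- labelComponents(mask, connectivity)
  comp <- componentSummary(lab)
  ord <- order(-comp$size, comp$firstIndex)
  comp <- comp[ord, , drop = FALSE]
  row.names(comp) <- NULL
  comp$selected <- seq_len(nrow(comp)) <= k
  out <- matrix(lab %in% comp$label[comp$selected], nrow(mask), ncol(mask))
  list(mask = out, components = comp)
}

## internal: lattice points exactly on the segment between two integer
## points (degenerate hull of collinear pixel sets)
segmentPixels <- function(p1, p2, dims) {
  d <- p2 - p1
  g <- max(1L, abs(gcdInt(d[1L], d[2L])))
  step <- d / g                                # integer lattice step
  pts <- t(vapply(0:g, function(k) p1 + k * step, numeric(2)))
  out <- matrix(FALSE, dims[1L], dims[2L])
  out[cbind(round(pts[, 1L]), round(pts[, 2L]))] <- TRUE
  out
}

gcdInt <- function(a, b) {
  a <- abs(as.integer(a)); b <- abs(as.integer(b))
  while (b != 0L) { t <- b; b <- a %% b; a <- t }
  a
}

#' Rasterized convex hull of a binary mask
#'
#' Computes the convex hull of the centres of all `TRUE` pixels and returns
#' the mask of every pixel whose centre lies inside or on the hull. The
#' result is always a superset of the input; applying the operation twice
#' equals applying it once. Degenerate inputs (empty, single pixel,
#' collinear pixels) return respectively an empty mask, the pixel itself,
#' and the lattice points on the extreme segment.
#'
#' @param mask logical matrix.
#' @return logical matrix.
#' @export
convexHullMask <- function(mask) {
  mask <- mask != 0
  pts <- which(mask, arr.ind = TRUE)
  if (nrow(pts) <= 1L) return(mask)
  r <- pts[, 1L]; c <- pts[, 2L]

  ## collinearity: cross products of all points against the extreme pair
  o <- order(r, c)
  p1 <- c(r[o[1L]], c[o[1L]]); p2 <- c(r[o[length(o)]], c[o[length(o)]])
  cross <- (p2[1L] - p1[1L]) * (c - p1[2L]) - (p2[2L] - p1[2L]) * (r - p1[1L])
  if (all(cross == 0)) {
    ## all pixels on one line: hull is the extreme segment
    proj <- (r - p1[1L]) * (p2[1L] - p1[1L]) + (c - p1[2L]) * (p2[2L] - p1[2L])
    a <- which.min(proj); b <- which.max(proj)
    return(segmentPixels(c(r[a], c[a]), c(r[b], c[b]), dim(mask)))
  }

  h <- grDevices::chull(c, r)                  # vertex indices
  vr <- r[h]; vc <- c[h]
  nv <- length(h)
  nxt <- c(seq_len(nv)[-1L], 1L)
  er <- vr[nxt] - vr; ec <- vc[nxt] - vc

  rlo <- min(vr); rhi <- max(vr); clo <- min(vc); chi <- max(vc)
  gr <- matrix(rlo:rhi, rhi - rlo + 1L, chi - clo + 1L)
  gc <- matrix(clo:chi, rhi - rlo + 1L, chi - clo + 1L, byrow = TRUE)
  inside <- matrix(TRUE, nrow(gr), ncol(gr))
  pos <- FALSE; neg <- FALSE
  crossAll <- vector("list", nv)
  for (k in seq_len(nv)) {
    cr <- er[k] * (gc - vc[k]) - ec[k] * (gr - vr[k])
    crossAll[[k]] <- cr
  }
  ## orientation from the polygon's signed area
  area2 <- sum(vr * vc[nxt] - vr[nxt] * vc)
  s <- if (area2 >= 0) 1 else -1
  for (k in seq_len(nv)) inside <- inside & (s * crossAll[[k]] >= 0)

  out <- matrix(FALSE, nrow(mask), ncol(mask))
  out[rlo:rhi, clo:chi][inside] <- TRUE
  out | mask
}

#' Segment the activation area of an activity map
#'
#' The full segmentation chain: threshold at `mean + kSd * SD` within the
#' trepanation ([thresholdActivity()]), remove connected components smaller
#' than `minSize` pixels ([removeSmallComponents()]), keep the `k` largest
#' components as the activation area ([selectLargestComponents()]) and
#' rasterize the convex hull of that activation ([convexHullMask()]).
#'
#' @param map an [ActivityMap-class] or numeric matrix.
#' @param trepanation logical matrix (or a [RegionMaskSet-class], whose
#'   trepanation is used).
#' @param kSd SD multiplier for the threshold (default 1).
#' @param minSize minimum component size in pixels (default 10).
#' @param k number of components kept (default 3).
#' @param connectivity 8 (default) or 4.
#' @return An [ActivationSegmentation-class].
#' @examples
#' m <- matrix(0, 8, 8); m[3:5, 3:5] <- 5
#' trep <- matrix(TRUE, 8, 8)
#' seg <- segmentActivation(m, trep, minSize = 4)
#' seg
#' @export
segmentActivation <- function(map, trepanation, kSd = 1, minSize = 10,
                              k = 3, connectivity = 8) {
  if (is(trepanation, "RegionMaskSet")) trepanation <- trepanation@trepanation
  th <- thresholdActivity(map, trepanation, kSd = kSd)
  opened <- removeSmallComponents(th$mask, minSize = minSize,
                                  connectivity = connectivity)
  sel <- selectLargestComponents(opened, k = k, connectivity = connectivity)
  hull <- convexHullMask(sel$mask)
  new("ActivationSegmentation",
      zThresh = th$zThresh, thresholdedMap = th$mask, openedMap = opened,
      activation = sel$mask, hull = hull, components = sel$components,
      parameters = list(kSd = kSd, minSize = minSize, k = k,
                        connectivity = connectivity))
}
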