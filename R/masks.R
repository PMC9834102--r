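#' Construct a region mask set
#'
#' @param trepanation logical matrix marking the craniotomy window.
#' @param psc optional logical matrix, primary sensory cortex segmentation.
#' @param referenceActivation optional logical matrix, e.g. an fMRI-derived
#'   activation registered into camera space.
#'
#' @details Masks are coerced to logical (any nonzero value is `TRUE`).
#' The expected nesting — reference within PSC within trepanation — is
#' checked and violations are reported as warnings, not errors; comparison
#' operations restrict masks to the relevant domain themselves.
#'
#' @return A [RegionMaskSet-class].
#' @export
regionMaskSet <- function(trepanation, psc = NULL,
                          referenceActivation = NULL) {
  asMask <- function(m) {
    if (is.null(m)) return(NULL)
    stopifnot(is.matrix(m))
    array(m != 0, dim = dim(m))
  }
  trepanation <- asMask(trepanation)
  psc <- asMask(psc)
  referenceActivation <- asMask(referenceActivation)
  obj <- new("RegionMaskSet", trepanation = trepanation, psc = psc,
             referenceActivation = referenceActivation)
  if (!is.null(psc) && any(psc & !trepanation))
    warning(sum(psc & !trepanation),
            " PSC pixels lie outside the trepanation")
  if (!is.null(referenceActivation)) {
    if (any(referenceActivation & !trepanation))
      warning(sum(referenceActivation & !trepanation),
              " reference-activation pixels lie outside the trepanation")
    if (!is.null(psc) && any(referenceActivation & !psc))
      warning(sum(referenceActivation & !psc),
              " reference-activation pixels lie outside the PSC")
  }
  obj
}
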