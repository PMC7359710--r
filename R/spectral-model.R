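#' Restrict an image to a wavenumber range
#'
#' Keeps the grid points with `lo <= wavenumber <= hi` (closed interval on
#' grid values, matching how spectral regions are conventionally quoted,
#' e.g. "900-1800 cm^-1"). Geometry and grid order are preserved.
#'
#' @param img a [HyperImage-class].
#' @param lo,hi numeric bounds in cm^-1, `lo < hi`.
#' @return A [HyperImage-class] restricted to the requested range.
#' @export
cutRange <- function(img, lo, hi) {
  stopifnot(is(img, "HyperImage"), lo < hi)
  wn <- img@wavenumber
  keep <- wn >= lo & wn <= hi
  if (!any(keep))
    stop(sprintf("cut range [%g, %g] contains no grid points (grid spans [%g, %g])",
                 lo, hi, min(wn), max(wn)))
  HyperImage(img@spectra[, keep, drop = FALSE], wn[keep], dims = img@dims,
             log = c(img@log, sprintf("cut to [%g, %g] cm-1", lo, hi)))
}

#' Normalize each spectrum of an image
#'
#' Divides every pixel spectrum by its own statistic: mean, L2 norm, maximum,
#' or the intensity at the grid point nearest a given wavenumber (`at_wn`,
#' e.g. the Amide I peak around 1650 cm^-1). Pixels whose divisor is zero are
#' left unchanged with a warning naming them, so degenerate (all-zero)
#' spectra survive the pipeline.
#'
#' @param img a [HyperImage-class].
#' @param method one of `"mean"`, `"l2"`, `"max"`, `"at_wn"`.
#' @param wn wavenumber (cm^-1) for `method = "at_wn"`; must lie within the
#'   grid span. The nearest grid point is used (no interpolation).
#' @return A [HyperImage-class] with normalized spectra.
#' @export
normalizeSpectra <- function(img, method = c("mean", "l2", "max", "at_wn"),
                             wn = NULL) {
  stopifnot(is(img, "HyperImage"))
  method <- match.arg(method)
  X <- img@spectra
  div <- switch(method,
    mean = rowMeans(X),
    l2 = sqrt(rowSums(X^2)),
    max = apply(X, 1L, max),
    at_wn = {
      grid <- img@wavenumber
      if (is.null(wn) || wn < min(grid) || wn > max(grid))
        stop("method 'at_wn' requires a wavenumber within the grid span")
      X[, which.min(abs(grid - wn))]
    })
  bad <- !is.finite(div) | div == 0
  if (any(bad)) {
    warning(sprintf("normalization divisor zero/non-finite for %d pixel(s) (e.g. pixel %d); left unchanged",
                    sum(bad), which(bad)[1]))
    div[bad] <- 1
  }
  HyperImage(X / div, img@wavenumber, dims = img@dims,
             log = c(img@log, paste0("normalized by ", method,
                                     if (method == "at_wn") sprintf(" (%g cm-1)", wn) else "")))
}

#' Interpolate a reference spectrum onto a grid
#'
#' Linear interpolation of a [ReferenceSpectrum-class] onto an arbitrary
#' wavenumber grid. Outside the reference's span the value is 0, so
#' subtraction-style corrections become no-ops where the reference carries no
#' information.
#'
#' @param ref a [ReferenceSpectrum-class] (at least 2 points).
#' @param grid numeric target wavenumber vector.
#' @return Numeric vector of interpolated values, one per grid point.
#' @export
interpolateToGrid <- function(ref, grid) {
  stopifnot(is(ref, "ReferenceSpectrum"))
  if (length(ref@wavenumber) < 2)
    stop("reference spectrum must have at least 2 points")
  stats::approx(ref@wavenumber, ref@values, xout = grid,
                method = "linear", yleft = 0, yright = 0)$y
}
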