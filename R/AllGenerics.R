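#' Accessors for spectral objects
#'
#' `wavenumbers()` returns the wavenumber grid (cm^-1), `specMatrix()` the
#' pixels x wavenumbers absorbance matrix, `imageDims()` the `c(height,
#' width)` geometry, `nPixels()` / `nWavenumbers()` the matrix dimensions and
#' `wnStep()` the median absolute grid spacing.
#'
#' @param x a [HyperImage-class], [ReferenceSpectrum-class] or
#'   [Phantom-class] object.
#' @return `wavenumbers`: numeric vector; `specMatrix`: numeric matrix;
#'   `imageDims`: integer(2); `nPixels`, `nWavenumbers`: integer; `wnStep`:
#'   numeric scalar.
#' @name accessors
#' @aliases wavenumbers specMatrix imageDims nPixels nWavenumbers wnStep
NULL

#' @rdname accessors
#' @export
setGeneric("wavenumbers", function(x) standardGeneric("wavenumbers"))
#' @rdname accessors
#' @export
setGeneric("specMatrix", function(x) standardGeneric("specMatrix"))
#' @rdname accessors
#' @export
setGeneric("imageDims", function(x) standardGeneric("imageDims"))
#' @rdname accessors
#' @export
setGeneric("nPixels", function(x) standardGeneric("nPixels"))
#' @rdname accessors
#' @export
setGeneric("nWavenumbers", function(x) standardGeneric("nWavenumbers"))
#' @rdname accessors
#' @export
setGeneric("wnStep", function(x) standardGeneric("wnStep"))

setMethod("wavenumbers", "HyperImage", function(x) x@wavenumber)
setMethod("wavenumbers", "ReferenceSpectrum", function(x) x@wavenumber)
setMethod("wavenumbers", "Phantom", function(x) x@image@wavenumber)
setMethod("specMatrix", "HyperImage", function(x) x@spectra)
setMethod("specMatrix", "Phantom", function(x) x@image@spectra)
setMethod("imageDims", "HyperImage", function(x) x@dims)
setMethod("imageDims", "Phantom", function(x) x@image@dims)
setMethod("nPixels", "HyperImage", function(x) nrow(x@spectra))
setMethod("nPixels", "Phantom", function(x) nrow(x@image@spectra))
setMethod("nWavenumbers", "HyperImage", function(x) ncol(x@spectra))
setMethod("wnStep", "HyperImage", function(x) stats::median(abs(diff(x@wavenumber))))
setMethod("wnStep", "ReferenceSpectrum", function(x) stats::median(abs(diff(x@wavenumber))))

#' @rdname accessors
#' @param object object to display.
#' @export
setMethod("show", "HyperImage", function(object) {
  d <- object@dims
  geo <- if (anyNA(d)) "no geometry" else sprintf("%d x %d pixels", d[1], d[2])
  wn <- object@wavenumber
  cat(sprintf("HyperImage: %d spectra (%s), %d wavenumbers [%.1f, %.1f] cm-1\n",
              nrow(object@spectra), geo, length(wn),
              if (length(wn)) min(wn) else NA, if (length(wn)) max(wn) else NA))
  if (length(object@log))
    cat("  log:", paste(utils::tail(object@log, 3), collapse = "; "), "\n")
})

setMethod("show", "ReferenceSpectrum", function(object) {
  wn <- object@wavenumber
  cat(sprintf("ReferenceSpectrum '%s': %d points [%.1f, %.1f] cm-1\n",
              object@label, length(wn), min(wn), max(wn)))
})

setMethod("show", "Phantom", function(object) {
  cat(sprintf("Phantom (seed %d): %d components, contaminations: %s\n",
              object@seed, ncol(object@trueC),
              if (length(object@contamination))
                paste(names(object@contamination), collapse = ", ")
              else "none"))
  show(object@image)
})

setMethod("show", "MCRResult", function(object) {
  cat(sprintf("MCRResult: %d components, %d pixels, %d iterations, stop: %s, final error %.4g%%\n",
              ncol(object@conc), nrow(object@conc), length(object@residuals),
              object@stopReason, utils::tail(object@residuals, 1)))
})

#' MCR factor accessors
#'
#' `concentrations()` returns the non-negative concentration matrix C
#' (pixels-in-ROI x components); `pureSpectra()` the non-negative spectra
#' matrix S (components x wavenumbers); `residualHistory()` the
#' per-iteration relative Frobenius error in percent.
#'
#' @param x an [MCRResult-class].
#' @return Matrix or numeric vector as described.
#' @name mcr-accessors
#' @aliases concentrations pureSpectra residualHistory
NULL

#' @rdname mcr-accessors
#' @export
setGeneric("concentrations", function(x) standardGeneric("concentrations"))
#' @rdname mcr-accessors
#' @export
setGeneric("pureSpectra", function(x) standardGeneric("pureSpectra"))
#' @rdname mcr-accessors
#' @export
setGeneric("residualHistory", function(x) standardGeneric("residualHistory"))

setMethod("concentrations", "MCRResult", function(x) x@conc)
setMethod("pureSpectra", "MCRResult", function(x) x@spec)
setMethod("residualHistory", "MCRResult", function(x) x@residuals)

setMethod("show", "SegmentationMap", function(object) {
  cat(sprintf("SegmentationMap: k = %d (%s normalization), %d pixels (%d excluded)\n",
              object@k, object@normalization, length(object@labels),
              sum(is.na(object@labels))))
})
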