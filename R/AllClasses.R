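#' @import methods
NULL

#' Hyperspectral image
#'
#' A hyperspectral image holds one absorbance spectrum per pixel as a
#' `n_pixels x n_wavenumbers` matrix together with the shared wavenumber grid
#' (cm^-1). Wavenumbers are stored in ascending order internally; readers
#' record the original orientation in the processing log so writers can
#' restore it. Image geometry (`height`, `width`) is optional: plain spectral
#' matrices without spatial layout have `dims = c(NA, NA)`.
#'
#' @slot spectra numeric matrix, pixels in rows, wavenumbers in columns.
#' @slot wavenumber strictly increasing numeric vector of wavenumbers (cm^-1),
#'   one per column of `spectra`.
#' @slot dims integer of length 2, `c(height, width)`; `NA` when unknown.
#' @slot log character vector of applied processing steps (provenance).
#'
#' @aliases HyperImage-class
#' @exportClass HyperImage
setClass("HyperImage",
  representation(
    spectra = "matrix",
    wavenumber = "numeric",
    dims = "integer",
    log = "character"
  ),
  prototype(
    spectra = matrix(numeric(0), 0, 0),
    wavenumber = numeric(0),
    dims = c(NA_integer_, NA_integer_),
    log = character(0)
  )
)

setValidity("HyperImage", function(object) {
  msg <- character(0)
  wn <- object@wavenumber
  if (ncol(object@spectra) != length(wn))
    msg <- c(msg, "number of spectral columns must equal length of wavenumber grid")
  if (length(wn) >= 2 && any(diff(wn) <= 0))
    msg <- c(msg, "wavenumber grid must be strictly increasing")
  if (length(object@dims) != 2L)
    msg <- c(msg, "dims must have length 2")
  if (!anyNA(object@dims) &&
      prod(object@dims) != nrow(object@spectra))
    msg <- c(msg, sprintf("height x width (%d x %d) must equal number of pixels (%d)",
                          object@dims[1], object@dims[2], nrow(object@spectra)))
  if (length(msg)) msg else TRUE
})

#' Construct a HyperImage
#'
#' @param spectra numeric matrix (pixels x wavenumbers) or a 3-d array
#'   (height x width x wavenumbers), flattened row-major by pixel.
#' @param wavenumber numeric wavenumber vector (cm^-1); may be descending, in
#'   which case both the grid and the spectral columns are reversed to the
#'   canonical ascending order and the reversal is logged.
#' @param dims optional `c(height, width)`. Inferred from a 3-d `spectra`
#'   array; otherwise `NA` unless given.
#' @param log character vector of provenance entries.
#' @return A [HyperImage-class] object.
#' @export
HyperImage <- function(spectra, wavenumber, dims = NULL, log = character(0)) {
  if (length(dim(spectra)) == 3L) {
    dims <- dim(spectra)[1:2]
    spectra <- matrix(spectra, nrow = prod(dims), ncol = dim(spectra)[3])
  }
  spectra <- as.matrix(spectra)
  storage.mode(spectra) <- "double"
  dimnames(spectra) <- NULL
  wavenumber <- as.numeric(wavenumber)
  if (length(wavenumber) >= 2 && all(diff(wavenumber) < 0)) {
    wavenumber <- rev(wavenumber)
    spectra <- spectra[, rev(seq_len(ncol(spectra))), drop = FALSE]
    log <- c(log, "wavenumber axis reversed to ascending")
  }
  if (is.null(dims)) dims <- c(NA_integer_, NA_integer_)
  new("HyperImage", spectra = spectra, wavenumber = wavenumber,
      dims = as.integer(dims), log = log)
}

#' Reference spectrum
#'
#' A single labelled spectrum on its own wavenumber grid, e.g. an atmospheric
#' gas reference or an initial Mie-correction reference (casein, lignin,
#' Matrigel or a user-supplied scattering-free spectrum).
#'
#' @slot wavenumber strictly increasing numeric vector (cm^-1).
#' @slot values numeric absorbance values, same length as the grid.
#' @slot label character label, e.g. `"atmospheric"`.
#' @aliases ReferenceSpectrum-class
#' @exportClass ReferenceSpectrum
setClass("ReferenceSpectrum",
  representation(wavenumber = "numeric", values = "numeric", label = "character"),
  prototype(wavenumber = numeric(0), values = numeric(0), label = NA_character_)
)

setValidity("ReferenceSpectrum", function(object) {
  msg <- character(0)
  if (length(object@values) != length(object@wavenumber))
    msg <- c(msg, "values and wavenumber must have equal length")
  if (length(object@wavenumber) >= 2 && any(diff(object@wavenumber) <= 0))
    msg <- c(msg, "wavenumber grid must be strictly increasing")
  if (anyNA(object@values) || any(!is.finite(object@values)))
    msg <- c(msg, "values must be finite")
  if (length(msg)) msg else TRUE
})

#' Construct a ReferenceSpectrum
#'
#' @param wavenumber numeric grid (cm^-1); descending input is reversed.
#' @param values numeric absorbance values.
#' @param label character label.
#' @return A [ReferenceSpectrum-class] object.
#' @export
ReferenceSpectrum <- function(wavenumber, values, label = "reference") {
  wavenumber <- as.numeric(wavenumber); values <- as.numeric(values)
  if (length(wavenumber) >= 2 && all(diff(wavenumber) < 0)) {
    wavenumber <- rev(wavenumber); values <- rev(values)
  }
  new("ReferenceSpectrum", wavenumber = wavenumber, values = values,
      label = label)
}

#' Phantom image with ground truth
#'
#' A synthetic hyperspectral image together with the ground truth it was
#' generated from: non-negative concentration maps, non-negative pure
#' component spectra, per-pixel region labels, and a record of every injected
#' contamination (atmospheric factors, Mie distortion parameters, baseline
#' coefficients, noise sigma). The whole object regenerates bit-exactly from
#' `seed` and the generator arguments.
#'
#' @slot image the contaminated [HyperImage-class].
#' @slot trueC pixels x k non-negative concentration matrix.
#' @slot trueS k x n_wavenumbers non-negative pure spectra.
#' @slot labels integer per-pixel region id.
#' @slot contamination named list recording injected contaminations.
#' @slot seed integer master seed.
#' @aliases Phantom-class
#' @exportClass Phantom
setClass("Phantom",
  representation(image = "HyperImage", trueC = "matrix", trueS = "matrix",
                 labels = "integer", contamination = "list", seed = "integer"))

setValidity("Phantom", function(object) {
  msg <- character(0)
  if (any(object@trueC < 0)) msg <- c(msg, "trueC must be non-negative")
  if (any(object@trueS < 0)) msg <- c(msg, "trueS must be non-negative")
  if (nrow(object@trueC) != nrow(object@image@spectra))
    msg <- c(msg, "trueC rows must match image pixels")
  if (ncol(object@trueC) != nrow(object@trueS))
    msg <- c(msg, "trueC columns must match trueS rows")
  if (ncol(object@trueS) != length(object@image@wavenumber))
    msg <- c(msg, "trueS columns must match image grid")
  if (length(msg)) msg else TRUE
})

#' MCR-ALS decomposition result
#'
#' Access the factor matrices with [concentrations()] (the `C` matrix,
#' pixels-in-ROI x k) and [pureSpectra()] (the `S` matrix, k x
#' n_wavenumbers).
#'
#' @slot conc pixels-in-ROI x k non-negative concentration matrix (C).
#' @slot spec k x n_wavenumbers non-negative spectra matrix (S).
#' @slot residuals numeric per-iteration relative Frobenius error (percent).
#' @slot stopReason one of `"tol"`, `"max_iter"`, `"error_increase"`.
#' @slot roi logical per-pixel inclusion mask (length = pixels of the source
#'   matrix; all `TRUE` when no ROI was applied).
#' @slot config list of configuration values used.
#' @aliases MCRResult-class
#' @exportClass MCRResult
setClass("MCRResult",
  representation(conc = "matrix", spec = "matrix", residuals = "numeric",
                 stopReason = "character", roi = "logical", config = "list"))

setValidity("MCRResult", function(object) {
  msg <- character(0)
  if (any(object@conc < 0) || any(object@spec < 0))
    msg <- c(msg, "C and S must be non-negative")
  if (ncol(object@conc) != nrow(object@spec))
    msg <- c(msg, "C columns must match S rows")
  if (any(!is.finite(object@residuals)))
    msg <- c(msg, "residual history must be finite")
  if (length(msg)) msg else TRUE
})

#' Segmentation map
#'
#' Per-pixel integer cluster labels in `1..k`, with `NA` marking pixels
#' excluded by a region of interest. (On export, excluded pixels are written
#' as -1.)
#'
#' @slot labels integer per-pixel labels (`NA` = excluded).
#' @slot k integer number of clusters requested.
#' @slot normalization character, normalization applied to concentrations
#'   before clustering (`"none"`, `"sum"`, `"l2"`).
#' @slot seed integer clustering seed.
#' @slot dims integer `c(height, width)` or `NA`.
#' @aliases SegmentationMap-class
#' @exportClass SegmentationMap
setClass("SegmentationMap",
  representation(labels = "integer", k = "integer", normalization = "character",
                 seed = "integer", dims = "integer"))

setValidity("SegmentationMap", function(object) {
  msg <- character(0)
  lab <- object@labels[!is.na(object@labels)]
  if (length(lab) && (min(lab) < 1L || max(lab) > object@k))
    msg <- c(msg, "labels must lie in 1..k or be NA")
  if (length(msg)) msg else TRUE
})
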