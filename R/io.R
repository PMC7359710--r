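#' Read a hyperspectral image from file
#'
#' Supported dialects:
#' \describe{
#'   \item{`"csv"`}{Delimited text (comma or tab, dot decimal). Either the
#'     first row or the first column holds the wavenumber vector, detected by
#'     strict monotonicity; the remaining rows (or columns) are pixel
#'     spectra.}
#'   \item{`"mat"`}{Uncompressed MATLAB v5 container with a 2-D spectra
#'     variable and a wavenumber vector (variable names configurable).}
#' }
#' Geometry is taken from a JSON sidecar `<path>.geometry.json` (keys
#' `height`, `width`), from a `wh` variable in a MAT file, or inferred as
#' square when the pixel count is a perfect square.
#'
#' @param path input file.
#' @param dialect `"auto"` (by extension), `"csv"` or `"mat"`.
#' @param matVars named list of MAT variable names, default
#'   `list(spectra = "AB", wavenumber = "wn", geometry = "wh")`.
#' @return A [HyperImage-class].
#' @export
readImage <- function(path, dialect = c("auto", "csv", "mat"),
                      matVars = list(spectra = "AB", wavenumber = "wn",
                                     geometry = "wh")) {
  dialect <- match.arg(dialect)
  if (!file.exists(path)) stop("file not found: ", path)
  if (dialect == "auto")
    dialect <- if (grepl("\\.mat$", path, ignore.case = TRUE)) "mat" else "csv"
  if (dialect == "mat") {
    vars <- readMat5(path)
    sv <- matVars$spectra; wv <- matVars$wavenumber
    if (is.null(vars[[sv]]) || is.null(vars[[wv]]))
      stop(sprintf("MAT file lacks variables '%s'/'%s'; found: %s", sv, wv,
                   paste(names(vars), collapse = ", ")))
    X <- vars[[sv]]
    wn <- as.numeric(vars[[wv]])
    if (ncol(X) != length(wn) && nrow(X) == length(wn)) X <- t(X)
    dims <- if (!is.null(vars[[matVars$geometry]])) {
      wh <- as.numeric(vars[[matVars$geometry]])
      c(wh[2], wh[1])          # stored (width, height)
    } else .inferGeometry(path, nrow(X))
    return(.checkedImage(X, wn, dims, path))
  }
  M <- as.matrix(data.table::fread(path, header = FALSE))
  if (anyNA(M)) {
    bad <- which(is.na(M), arr.ind = TRUE)[1, ]
    stop(sprintf("NaN/missing cell at row %d, column %d of %s",
                 bad[1], bad[2], path))
  }
  isMono <- function(v) length(v) >= 2 &&
    (all(diff(v) > 0) || all(diff(v) < 0))
  rowCand <- isMono(M[1, ])
  colCand <- isMono(M[, 1])
  if (rowCand) {
    wn <- M[1, ]; X <- M[-1, , drop = FALSE]
  } else if (colCand) {
    wn <- M[, 1]; X <- t(M[, -1, drop = FALSE])
  } else {
    stop(sprintf(paste0("no monotone wavenumber vector found in %s ",
                        "(first row: [%g, %g, ...]; first column: [%g, %g, ...])"),
                 path, M[1, 1], M[1, 2], M[1, 1], M[2, 1]))
  }
  .checkedImage(X, wn, .inferGeometry(path, nrow(X)), path)
}

.inferGeometry <- function(path, npix) {
  sidecar <- paste0(path, ".geometry.json")
  if (file.exists(sidecar)) {
    g <- jsonlite::fromJSON(sidecar)
    return(c(g$height, g$width))
  }
  s <- sqrt(npix)
  if (s == round(s)) c(as.integer(s), as.integer(s))
  else c(NA_integer_, NA_integer_)
}

.checkedImage <- function(X, wn, dims, path) {
  if (!all(is.finite(X))) {
    bad <- which(!is.finite(X), arr.ind = TRUE)[1, ]
    stop(sprintf("non-finite value at pixel %d, wavenumber index %d of %s",
                 bad[1], bad[2], path))
  }
  HyperImage(X, wn, dims = dims, log = sprintf("read from %s", path))
}

#' Write a hyperspectral image to file
#'
#' CSV dialect writes the wavenumber vector as the first row followed by one
#' row per pixel, plus a JSON geometry sidecar when the geometry is known
#' and not square. MAT dialect writes uncompressed v5 variables (spectra,
#' wavenumber, geometry).
#'
#' @param img a [HyperImage-class].
#' @param path output path.
#' @param dialect `"auto"`, `"csv"` or `"mat"`.
#' @inheritParams readImage
#' @return `path`, invisibly.
#' @export
writeImage <- function(img, path, dialect = c("auto", "csv", "mat"),
                       matVars = list(spectra = "AB", wavenumber = "wn",
                                      geometry = "wh")) {
  stopifnot(is(img, "HyperImage"))
  dialect <- match.arg(dialect)
  if (dialect == "auto")
    dialect <- if (grepl("\\.mat$", path, ignore.case = TRUE)) "mat" else "csv"
  dims <- img@dims
  if (dialect == "mat") {
    vars <- stats::setNames(
      list(img@spectra, matrix(img@wavenumber, 1L)),
      c(matVars$spectra, matVars$wavenumber))
    if (!anyNA(dims))
      vars[[matVars$geometry]] <- matrix(as.numeric(c(dims[2], dims[1])), 1L)
    writeMat5(path, vars)
  } else {
    .writeNumericCsv(rbind(img@wavenumber, img@spectra), path)
    if (!anyNA(dims) && dims[1] != dims[2])
      jsonlite::write_json(list(height = dims[1], width = dims[2]),
                           paste0(path, ".geometry.json"), auto_unbox = TRUE)
  }
  invisible(path)
}

# Full-precision CSV writer: 17 significant digits round-trip doubles
# exactly through fread.
.writeNumericCsv <- function(M, path) {
  ch <- matrix(sprintf("%.17g", M), nrow(M), ncol(M))
  data.table::fwrite(data.table::as.data.table(ch), path, col.names = FALSE,
                     quote = FALSE)
  invisible(path)
}

#' Read a reference spectrum from a two-column delimited file
#'
#' @param path file with columns wavenumber, absorbance (no header, comma or
#'   tab separated).
#' @param label label for the resulting [ReferenceSpectrum-class].
#' @return A [ReferenceSpectrum-class].
#' @export
readReference <- function(path, label = basename(path)) {
  M <- as.matrix(data.table::fread(path, header = FALSE))
  if (ncol(M) < 2) stop("reference file must have two columns: ", path)
  ReferenceSpectrum(M[, 1], M[, 2], label = label)
}

#' Write a reference spectrum
#'
#' @param ref a [ReferenceSpectrum-class].
#' @param path output path (two columns: wavenumber, absorbance).
#' @return `path`, invisibly.
#' @export
writeReference <- function(ref, path) {
  stopifnot(is(ref, "ReferenceSpectrum"))
  .writeNumericCsv(cbind(ref@wavenumber, ref@values), path)
}

#' Write a segmentation label map
#'
#' Writes the labels as a delimited integer matrix (height x width,
#' ROI-excluded pixels as -1) and, optionally, a color PNG label image.
#'
#' @param seg a [SegmentationMap-class] with known geometry.
#' @param path output path for the delimited matrix.
#' @param png optional path for a PNG label image.
#' @return `path`, invisibly.
#' @export
writeLabelMap <- function(seg, path, png = NULL) {
  stopifnot(is(seg, "SegmentationMap"))
  if (anyNA(seg@dims)) stop("segmentation map has no geometry")
  lab <- seg@labels
  lab[is.na(lab)] <- -1L
  M <- matrix(lab, seg@dims[1], seg@dims[2], byrow = TRUE)
  data.table::fwrite(data.table::as.data.table(M), path, col.names = FALSE)
  if (!is.null(png)) {
    pal <- grDevices::col2rgb(grDevices::hcl.colors(seg@k, "Dark 3")) / 255
    arr <- array(0, c(seg@dims[1], seg@dims[2], 3))
    for (ch in 1:3) {
      chan <- ifelse(M > 0, pal[ch, pmax(M, 1)], 0)
      arr[, , ch] <- matrix(chan, seg@dims[1], seg@dims[2])
    }
    png::writePNG(arr, png)
  }
  invisible(path)
}
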