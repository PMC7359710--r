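# Minimal MATLAB v5 (Level 5 MAT-file) support for uncompressed numeric 2-D
# arrays, little-endian. Covers the de-facto interchange convention for
# hyperspectral images (a spectra matrix plus a wavenumber vector / geometry
# vector per file). Compressed (v7/zlib) and HDF5 (v7.3) files are rejected
# with a pointer to re-saving with -v6.

.mat5Types <- c(miINT8 = 1, miUINT8 = 2, miINT16 = 3, miUINT16 = 4,
                miINT32 = 5, miUINT32 = 6, miSINGLE = 7, miDOUBLE = 9,
                miINT64 = 12, miUINT64 = 13, miMATRIX = 14,
                miCOMPRESSED = 15, miUTF8 = 16)

#' Write matrices to a MATLAB v5 container
#'
#' Writes named numeric matrices/vectors as uncompressed double-precision
#' 2-D arrays in a little-endian Level 5 MAT-file, readable by MATLAB,
#' Octave and scipy.
#'
#' @param path output file path.
#' @param vars named list of numeric matrices or vectors (vectors are
#'   written as 1 x n row vectors).
#' @return `path`, invisibly.
#' @export
writeMat5 <- function(path, vars) {
  stopifnot(is.list(vars), !is.null(names(vars)), all(nzchar(names(vars))))
  con <- file(path, "wb")
  on.exit(close(con))
  desc <- sprintf("MATLAB 5.0 MAT-file, created by vibrospec")
  hdr <- charToRaw(desc)
  hdr <- c(hdr, rep(as.raw(0x20), 116 - length(hdr)))
  writeBin(hdr, con)
  writeBin(raw(8), con)                               # subsystem offset
  writeBin(as.raw(c(0x00, 0x01)), con)                # version 0x0100 (LE)
  writeBin(charToRaw("IM"), con)                      # endian indicator
  pad8 <- function(n) if (n %% 8) writeBin(raw(8 - n %% 8), con)
  for (nm in names(vars)) {
    v <- vars[[nm]]
    if (is.null(dim(v))) v <- matrix(as.numeric(v), nrow = 1L)
    v <- as.matrix(v); storage.mode(v) <- "double"
    nameRaw <- charToRaw(nm)
    nBytesName <- length(nameRaw)
    namePad <- (8 - nBytesName %% 8) %% 8
    totalBytes <- 8 + 8 +            # array flags
      8 + 8 +                        # dimensions (2 x int32, padded)
      8 + nBytesName + namePad +     # name
      8 + 8 * length(v)              # real data
    writeBin(c(14L, as.integer(totalBytes)), con, size = 4)   # miMATRIX
    writeBin(c(6L, 8L), con, size = 4)                        # array flags tag
    writeBin(c(6L, 0L), con, size = 4)                        # mxDOUBLE_CLASS
    writeBin(c(5L, 8L), con, size = 4)                        # dims tag
    writeBin(as.integer(dim(v)), con, size = 4)
    writeBin(c(1L, nBytesName), con, size = 4)                # name tag
    writeBin(nameRaw, con)
    if (namePad) writeBin(raw(namePad), con)
    writeBin(c(9L, as.integer(8 * length(v))), con, size = 4) # real data tag
    writeBin(as.numeric(v), con, size = 8)
  }
  invisible(path)
}

#' Read numeric matrices from a MATLAB v5 container
#'
#' Reads every uncompressed numeric 2-D array of a little-endian Level 5
#' MAT-file into a named list of double matrices. Compressed elements and
#' v7.3 (HDF5) files raise an error asking for an uncompressed (-v6) save;
#' non-numeric variables are skipped.
#'
#' @param path MAT file path.
#' @return Named list of numeric matrices.
#' @export
readMat5 <- function(path) {
  raw <- readBin(path, "raw", n = file.info(path)$size)
  if (length(raw) < 128) stop("not a MAT v5 file (too short): ", path)
  if (identical(rawToChar(raw[1:4]), "MATL") &&
      length(raw) >= 8 && raw[1] == as.raw(0x89))
    stop("HDF5-based v7.3 MAT files are not supported")
  endian <- rawToChar(raw[127:128])
  if (endian == "MI")
    stop("big-endian MAT files are not supported")
  if (endian != "IM") stop("not a MAT v5 file: ", path)
  pos <- 129L  # 1-based position after header
  out <- list()
  readU32 <- function(at) readBin(raw[at:(at + 3)], "integer", size = 4,
                                  endian = "little")
  while (pos + 7 <= length(raw)) {
    typeWord <- readU32(pos)
    small <- bitwAnd(typeWord, -65536L) != 0L   # small data element format
    if (small) stop("unexpected small element at top level")
    nbytes <- readU32(pos + 4L)
    dtype <- typeWord
    body <- raw[(pos + 8L):(pos + 7L + nbytes)]
    if (dtype == .mat5Types[["miCOMPRESSED"]])
      stop("compressed MAT element; re-save uncompressed (MATLAB: -v6, scipy: do_compression=False)")
    if (dtype == .mat5Types[["miMATRIX"]]) {
      parsed <- .mat5ParseMatrix(body)
      if (!is.null(parsed)) out[[parsed$name]] <- parsed$data
    }
    adv <- 8L + nbytes + (8L - nbytes %% 8L) %% 8L
    pos <- pos + adv
  }
  out
}

# Parse one miMATRIX element body; returns list(name, data) or NULL for
# unsupported classes.
.mat5ParseMatrix <- function(body) {
  pos <- 1L
  readU32 <- function(at) readBin(body[at:(at + 3)], "integer", size = 4,
                                  endian = "little")
  readSub <- function() {
    typeWord <- readU32(pos)
    small <- bitwAnd(typeWord, -65536L) != 0L
    if (small) {
      dtype <- bitwAnd(typeWord, 65535L)
      nb <- bitwShiftR(bitwAnd(typeWord, -65536L), 16L)
      dat <- if (nb > 0) body[(pos + 4L):(pos + 3L + nb)] else raw(0)
      pos <<- pos + 8L
    } else {
      dtype <- typeWord
      nb <- readU32(pos + 4L)
      dat <- if (nb > 0) body[(pos + 8L):(pos + 7L + nb)] else raw(0)
      pos <<- pos + 8L + nb + (8L - nb %% 8L) %% 8L
    }
    list(type = dtype, bytes = dat)
  }
  flags <- readSub()
  klass <- as.integer(flags$bytes[1])
  dims <- readSub()
  dimv <- readBin(dims$bytes, "integer", n = length(dims$bytes) / 4,
                  size = 4, endian = "little")
  nameEl <- readSub()
  name <- rawToChar(nameEl$bytes)
  # numeric classes: mxDOUBLE 6, mxSINGLE 7, mxINT8..mxUINT32 8..13
  if (!(klass %in% 6:13) || length(dimv) != 2L) return(NULL)
  dataEl <- readSub()
  vals <- switch(as.character(dataEl$type),
    `9` = readBin(dataEl$bytes, "double", n = length(dataEl$bytes) / 8,
                  size = 8, endian = "little"),
    `7` = readBin(dataEl$bytes, "double", n = length(dataEl$bytes) / 4,
                  size = 4, endian = "little"),
    `1` = as.numeric(readBin(dataEl$bytes, "integer",
                             n = length(dataEl$bytes), size = 1,
                             endian = "little")),
    `2` = as.numeric(readBin(dataEl$bytes, "integer",
                             n = length(dataEl$bytes), size = 1, signed = FALSE,
                             endian = "little")),
    `3` = as.numeric(readBin(dataEl$bytes, "integer",
                             n = length(dataEl$bytes) / 2, size = 2,
                             endian = "little")),
    `4` = as.numeric(readBin(dataEl$bytes, "integer",
                             n = length(dataEl$bytes) / 2, size = 2,
                             signed = FALSE, endian = "little")),
    `5` = as.numeric(readBin(dataEl$bytes, "integer",
                             n = length(dataEl$bytes) / 4, size = 4,
                             endian = "little")),
    `6` = as.numeric(readBin(dataEl$bytes, "integer",
                             n = length(dataEl$bytes) / 4, size = 4,
                             endian = "little")),
    stop("unsupported MAT data type ", dataEl$type))
  list(name = name, data = matrix(vals, dimv[1], dimv[2]))
}
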