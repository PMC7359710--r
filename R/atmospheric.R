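#' Options for atmospheric gas correction
#'
#' Defaults follow the documented correction procedure: water vapor is
#' removed independently in the 1300-2100 and 3410-3850 cm^-1 regions, CO2 in
#' 2280-2430 cm^-1 (either by the same subtraction or by replacement with a
#' non-overshooting spline). Optional windowed refinement repeats the fit in
#' narrow windows (60 cm^-1 in the low water region, 300 cm^-1 in the high
#' one, 80 cm^-1 for CO2), 5 passes with gain 1/4. Optional smoothing applies
#' a third-order Savitzky-Golay filter with a nine-point window inside the
#' corrected regions only.
#'
#' @param waterRegions list of `c(lo, hi)` water-vapor regions (cm^-1).
#' @param waterWindows numeric refinement window width per water region (cm^-1).
#' @param co2Region `c(lo, hi)` CO2 region.
#' @param co2Mode `"subtract"` (same method as water), `"spline"`
#'   (replace the whole region with a monotone spline) or `"none"`.
#' @param co2Window refinement window width for the CO2 region (cm^-1).
#' @param extraWindowed logical, apply windowed refinement after the global
#'   subtraction.
#' @param passes integer refinement passes.
#' @param gain per-pass refinement gain in (0, 1].
#' @param smooth logical, Savitzky-Golay smoothing inside corrected regions.
#' @param sgOrder,sgWindow Savitzky-Golay polynomial order and window (points).
#' @return A named list of class `"AtmOptions"`.
#' @export
atmOptions <- function(waterRegions = list(c(1300, 2100), c(3410, 3850)),
                       waterWindows = c(60, 300),
                       co2Region = c(2280, 2430),
                       co2Mode = c("subtract", "spline", "none"),
                       co2Window = 80,
                       extraWindowed = TRUE,
                       passes = 5L, gain = 0.25,
                       smooth = TRUE, sgOrder = 3L, sgWindow = 9L) {
  co2Mode <- match.arg(co2Mode)
  stopifnot(length(waterRegions) == length(waterWindows),
            gain > 0, gain <= 1, passes >= 0,
            sgWindow %% 2 == 1, sgWindow > sgOrder)
  regs <- c(waterRegions, list(co2Region))
  regs <- regs[order(vapply(regs, `[`, 0, 1))]
  for (i in seq_along(regs)[-1])
    if (regs[[i]][1] < regs[[i - 1]][2])
      stop("correction regions must not overlap")
  structure(list(waterRegions = waterRegions, waterWindows = waterWindows,
                 co2Region = co2Region, co2Mode = co2Mode,
                 co2Window = co2Window, extraWindowed = extraWindowed,
                 passes = as.integer(passes), gain = gain, smooth = smooth,
                 sgOrder = as.integer(sgOrder), sgWindow = as.integer(sgWindow)),
            class = "AtmOptions")
}

#' Derivative-smoothness subtraction factor
#'
#' Scale factor `a` minimizing the sum of squared first differences of
#' `x - a * r`, i.e. `a = sum(dx * dr) / sum(dr^2)` with `dx[j] = x[j] -
#' x[j-1]`. Differences are taken between adjacent grid points in ascending
#' wavenumber order, with no spacing normalization (the criterion is
#' index-based). `a` may be negative; a flat reference in the segment yields
#' `a = 0` with a warning.
#'
#' @param x numeric spectrum segment (length >= 2).
#' @param r numeric reference segment, same length.
#' @return Scalar factor `a`.
#' @export
fitFactor <- function(x, r) {
  stopifnot(length(x) == length(r), length(x) >= 2)
  dx <- diff(x); dr <- diff(r)
  den <- sum(dr^2)
  if (den == 0) {
    warning("flat reference in region; factor set to 0")
    return(0)
  }
  sum(dx * dr) / den
}

# Matrix variant: one factor per row of X (pixels), shared reference r.
.fitFactorMat <- function(X, r) {
  dX <- X[, -1L, drop = FALSE] - X[, -ncol(X), drop = FALSE]
  dr <- diff(r)
  den <- sum(dr^2)
  if (den == 0) return(rep(0, nrow(X)))
  as.numeric(dX %*% dr) / den
}

.regionIdx <- function(grid, region) which(grid >= region[1] & grid <= region[2])

#' Subtract a scaled reference inside one region
#'
#' Computes the [fitFactor()] on the region and subtracts `a * r` at the grid
#' points inside the region only; everything outside is untouched. Operates
#' on a pixels x wavenumbers matrix (or a single spectrum vector).
#'
#' @param X numeric matrix (pixels x wavenumbers) or vector.
#' @param grid wavenumber vector matching the columns of `X`.
#' @param r reference spectrum on the same grid (full length).
#' @param region `c(lo, hi)` in cm^-1.
#' @return List with `x` (corrected matrix/vector) and `a` (per-pixel factor
#'   vector). A region outside the grid span is a no-op with a warning
#'   (`a = 0`).
#' @export
subtractRegion <- function(X, grid, r, region) {
  vec <- is.null(dim(X))
  if (vec) X <- matrix(X, nrow = 1L)
  idx <- .regionIdx(grid, region)
  if (length(idx) < 2) {
    warning(sprintf("region [%g, %g] outside grid span; no correction applied",
                    region[1], region[2]))
    a <- rep(0, nrow(X))
  } else {
    a <- .fitFactorMat(X[, idx, drop = FALSE], r[idx])
    X[, idx] <- X[, idx, drop = FALSE] - outer(a, r[idx])
  }
  list(x = if (vec) X[1L, ] else X, a = a)
}

#' Windowed refinement of an atmospheric subtraction
#'
#' After the global per-region subtraction, residual gas lines of locally
#' varying intensity are reduced by repeating the factor fit in a narrow
#' window around every grid point `j` of the region and updating
#' `x[j] <- x[j] - gain * a_j * r[j]`. Updates within one pass are
#' simultaneous (order independent); windows are truncated at the region
#' edges.
#'
#' @inheritParams subtractRegion
#' @param window window width in cm^-1 (must span at least 3 grid points).
#' @param passes number of passes (0 = identity).
#' @param gain update gain, default 1/4.
#' @return Corrected matrix (or vector, matching the input shape).
#' @export
windowedRefinement <- function(X, grid, r, region, window, passes = 5L,
                               gain = 0.25) {
  vec <- is.null(dim(X))
  if (vec) X <- matrix(X, nrow = 1L)
  idx <- .regionIdx(grid, region)
  if (length(idx) < 3 || passes < 1)
    return(if (vec) X[1L, ] else X)
  g <- grid[idx]
  if (window <= 2 * stats::median(diff(g)))
    stop("refinement window must span at least 3 grid points")
  m <- length(idx)
  rr <- r[idx]
  lw <- findInterval(g - window / 2 - 1e-9, g) + 1L
  hw <- findInterval(g + window / 2 + 1e-9, g)
  dr <- diff(rr)
  csd <- c(0, cumsum(dr^2))
  den <- csd[hw] - csd[lw]          # sum of dr^2 over pairs inside window
  den[den == 0] <- Inf
  rmat <- matrix(rr, nrow(X), m, byrow = TRUE)
  for (p in seq_len(passes)) {
    Xr <- X[, idx, drop = FALSE]
    W <- (Xr[, -1L, drop = FALSE] - Xr[, -m, drop = FALSE]) *
      matrix(dr, nrow(X), m - 1L, byrow = TRUE)
    CS <- cbind(0, W)
    for (jj in seq(3L, m))   # running sum along wavenumber axis
      CS[, jj] <- CS[, jj] + CS[, jj - 1L]
    A <- (CS[, hw, drop = FALSE] - CS[, lw, drop = FALSE]) /
      matrix(den, nrow(X), m, byrow = TRUE)
    X[, idx] <- Xr - gain * A * rmat
  }
  if (vec) X[1L, ] else X
}

#' Replace the CO2 region with a non-overshooting spline
#'
#' Values strictly inside the region are replaced by a monotonicity
#' preserving (PCHIP) cubic interpolant anchored at `nAnchor` grid points on
#' each side of the region, guaranteeing no overshoot beyond the anchor
#' values. A region at the grid edge falls back to linear extension from the
#' available side.
#'
#' @inheritParams subtractRegion
#' @param nAnchor anchor points per side (default 4).
#' @return Corrected matrix (or vector, matching the input shape).
#' @export
replaceCO2Spline <- function(X, grid, region, nAnchor = 4L) {
  vec <- is.null(dim(X))
  if (vec) X <- matrix(X, nrow = 1L)
  idx <- .regionIdx(grid, region)
  if (!length(idx)) return(if (vec) X[1L, ] else X)
  left <- seq(max(1L, min(idx) - nAnchor), min(idx) - 1L)
  left <- left[left >= 1]
  right <- seq(max(idx) + 1L, min(length(grid), max(idx) + nAnchor))
  right <- right[right <= length(grid)]
  anch <- c(left, right)
  if (length(left) && length(right)) {
    for (i in seq_len(nrow(X)))
      X[i, idx] <- pracma::pchip(grid[anch], X[i, anch], grid[idx])
  } else if (length(anch) >= 2) {
    # one-sided: linear extension from the available anchors
    for (i in seq_len(nrow(X))) {
      fit <- stats::lm.fit(cbind(1, grid[anch]), X[i, anch])
      X[i, idx] <- fit$coefficients[1] + fit$coefficients[2] * grid[idx]
    }
  }
  if (vec) X[1L, ] else X
}

#' Savitzky-Golay smoothing restricted to regions
#'
#' The filter is computed on the full spectrum and the result spliced into
#' the given regions only, so seams at region borders come from a filter that
#' saw the whole spectrum.
#'
#' @inheritParams subtractRegion
#' @param regions list of `c(lo, hi)` regions.
#' @param order,window Savitzky-Golay order and window length (odd).
#' @return Smoothed matrix (or vector, matching the input shape).
#' @export
regionSmooth <- function(X, grid, regions, order = 3L, window = 9L) {
  vec <- is.null(dim(X))
  if (vec) X <- matrix(X, nrow = 1L)
  idx <- sort(unique(unlist(lapply(regions, .regionIdx, grid = grid))))
  if (length(idx)) {
    for (i in seq_len(nrow(X))) {
      sm <- signal::sgolayfilt(X[i, ], p = order, n = window)
      X[i, idx] <- sm[idx]
    }
  }
  if (vec) X[1L, ] else X
}

#' Atmospheric gas correction pipeline
#'
#' Per spectrum: global scaled subtraction of the atmospheric reference in
#' each water region independently, CO2 handling per `co2Mode`, optional
#' windowed refinement per region (each with its own window width), and
#' optional Savitzky-Golay smoothing inside the corrected regions. Spectra
#' outside all regions are untouched.
#'
#' @param img a [HyperImage-class].
#' @param atmRef a [ReferenceSpectrum-class] with the atmospheric gas
#'   spectrum (interpolated onto the image grid; zero outside its span).
#' @param opts an [atmOptions()] list.
#' @return List with `image` (corrected [HyperImage-class]), `factors`
#'   (pixels x regions matrix of subtraction factors; `NA` for a
#'   spline-replaced CO2 region) and `options`.
#' @export
atmosphericPipeline <- function(img, atmRef, opts = atmOptions()) {
  stopifnot(is(img, "HyperImage"), is(atmRef, "ReferenceSpectrum"),
            inherits(opts, "AtmOptions"))
  grid <- img@wavenumber
  r <- interpolateToGrid(atmRef, grid)
  allReg <- c(opts$waterRegions,
              if (opts$co2Mode != "none") list(opts$co2Region))
  if (length(allReg) && !any(vapply(allReg, function(reg) {
        i <- .regionIdx(grid, reg); length(i) > 1 && any(r[i] != 0)
      }, TRUE)))
    stop("atmospheric reference does not overlap any correction region: ",
         paste(vapply(allReg, function(z) sprintf("[%g, %g]", z[1], z[2]), ""),
               collapse = ", "))
  X <- img@spectra
  nreg <- length(opts$waterRegions) + 1L
  factors <- matrix(NA_real_, nrow(X), nreg,
                    dimnames = list(NULL, c(sprintf("water_%d",
                                                    seq_along(opts$waterRegions)),
                                            "co2")))
  smoothed <- list()
  for (i in seq_along(opts$waterRegions)) {
    reg <- opts$waterRegions[[i]]
    res <- subtractRegion(X, grid, r, reg)
    X <- res$x
    factors[, i] <- res$a
    if (opts$extraWindowed && opts$passes > 0)
      X <- windowedRefinement(X, grid, r, reg, opts$waterWindows[i],
                              passes = opts$passes, gain = opts$gain)
    smoothed <- c(smoothed, list(reg))
  }
  if (opts$co2Mode == "subtract") {
    res <- subtractRegion(X, grid, r, opts$co2Region)
    X <- res$x
    factors[, nreg] <- res$a
    if (opts$extraWindowed && opts$passes > 0)
      X <- windowedRefinement(X, grid, r, opts$co2Region, opts$co2Window,
                              passes = opts$passes, gain = opts$gain)
    smoothed <- c(smoothed, list(opts$co2Region))
  } else if (opts$co2Mode == "spline") {
    X <- replaceCO2Spline(X, grid, opts$co2Region)
  }
  if (opts$smooth && length(smoothed))
    X <- regionSmooth(X, grid, smoothed, order = opts$sgOrder,
                      window = opts$sgWindow)
  out <- HyperImage(X, grid, dims = img@dims,
                    log = c(img@log, sprintf("atmospheric correction (co2 %s)",
                                             opts$co2Mode)))
  list(image = out, factors = factors, options = opts)
}
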