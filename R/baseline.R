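#' Savitzky-Golay denoising of whole spectra
#'
#' Per-spectrum Savitzky-Golay smoothing over the full wavenumber range.
#' Polynomials of degree at most `order` pass through unchanged.
#'
#' @param img a [HyperImage-class].
#' @param order polynomial order.
#' @param window window length in points (odd, greater than `order`).
#' @return A smoothed [HyperImage-class].
#' @export
sgDenoise <- function(img, order = 3L, window = 9L) {
  stopifnot(is(img, "HyperImage"), window %% 2 == 1, window > order)
  X <- img@spectra
  for (i in seq_len(nrow(X)))
    X[i, ] <- signal::sgolayfilt(X[i, ], p = order, n = window)
  HyperImage(X, img@wavenumber, dims = img@dims,
             log = c(img@log, sprintf("SG denoise (order %d, window %d)",
                                      order, window)))
}

#' Rubberband baseline
#'
#' The baseline is the lower convex hull of the points `(wavenumber, x)`,
#' evaluated piecewise-linearly between its supporting points. It never
#' exceeds the spectrum and touches it at both endpoints.
#'
#' @param x numeric spectrum.
#' @param grid wavenumber vector, same length.
#' @return Numeric baseline vector, `baseline <= x` everywhere.
#' @export
rubberband <- function(x, grid) {
  stopifnot(length(x) == length(grid), length(x) >= 2)
  n <- length(x)
  # Andrew's monotone chain, lower hull only (grid is ascending)
  hull <- integer(n)
  m <- 0L
  for (i in seq_len(n)) {
    while (m >= 2L) {
      # cross product of (hull[m-1] -> hull[m]) x (hull[m-1] -> i)
      cr <- (grid[hull[m]] - grid[hull[m - 1L]]) * (x[i] - x[hull[m - 1L]]) -
            (x[hull[m]] - x[hull[m - 1L]]) * (grid[i] - grid[hull[m - 1L]])
      if (cr <= 0) m <- m - 1L else break
    }
    m <- m + 1L
    hull[m] <- i
  }
  hull <- hull[seq_len(m)]
  stats::approx(grid[hull], x[hull], xout = grid)$y
}

#' Iterated concave rubberband baseline
#'
#' Repeatedly subtracts a concave parabola (zero at the spectrum ends, unit
#' peak in the middle, scaled by an amplitude that starts at a quarter of the
#' spectrum's range and is halved each iteration) before taking the
#' rubberband, then adds it back to the resulting hull. This flattens
#' concave-curved baselines so the convex hull can follow them. The final
#' baseline is the pointwise maximum over iterations and never exceeds the
#' spectrum.
#'
#' @inheritParams rubberband
#' @param iterations number of parabola iterations; 0 gives the plain
#'   rubberband.
#' @param tol early-exit tolerance on the baseline change.
#' @return Numeric baseline vector, `baseline <= x` everywhere.
#' @export
concaveRubberband <- function(x, grid, iterations = 10L, tol = 1e-10) {
  base <- rubberband(x, grid)
  if (iterations < 1) return(base)
  span <- max(grid) - min(grid)
  parab <- 4 * (grid - min(grid)) * (max(grid) - grid) / span^2
  amp <- (max(x) - min(x)) / 4
  for (i in seq_len(iterations)) {
    cand <- rubberband(x - amp * parab, grid) + amp * parab
    newBase <- pmax(base, cand)
    if (max(abs(newBase - base)) < tol) { base <- newBase; break }
    base <- newBase
    amp <- amp / 2
  }
  base
}

# Sparse second-difference penalty matrix (lambda * D'D), n x n.
.d2Penalty <- function(n, lambda) {
  D <- Matrix::bandSparse(n - 2L, n, k = 0:2,
                          diagonals = list(rep(1, n - 2L), rep(-2, n - 2L),
                                           rep(1, n - 2L)))
  lambda * Matrix::crossprod(D)
}

#' Asymmetric least squares (AsLS) baseline
#'
#' Iterates the penalized least-squares problem
#' `min sum(w (x - z)^2) + lambda sum(diff(z, 2)^2)` with asymmetric weights:
#' `p` where `x > z` and `1 - p` where `x <= z`, so the smooth baseline `z`
#' hugs the underside of positive peaks.
#'
#' @param x numeric spectrum.
#' @param lambda smoothness penalty (> 0), default 1e6.
#' @param p asymmetry in (0, 1), default 0.01.
#' @param maxIter weight-update iterations.
#' @return Numeric baseline vector.
#' @export
asls <- function(x, lambda = 1e6, p = 0.01, maxIter = 10L) {
  stopifnot(lambda > 0, p > 0, p < 1)
  n <- length(x)
  P <- .d2Penalty(n, lambda)
  w <- rep(1, n)
  z <- x
  for (i in seq_len(maxIter)) {
    W <- Matrix::Diagonal(n, w)
    z <- as.numeric(Matrix::solve(W + P, w * x))
    wNew <- ifelse(x > z, p, 1 - p)
    if (all(wNew == w)) break
    w <- wNew
  }
  z
}

#' Asymmetrically reweighted penalized least squares (arPLS) baseline
#'
#' Like [asls()] but the weights adapt to the residual distribution through a
#' logistic function of `d = x - z`: points far above the baseline (peaks)
#' are progressively down-weighted relative to the noise level of the
#' below-baseline residuals. Terminates when the relative weight change drops
#' below `ratio`.
#'
#' @param x numeric spectrum.
#' @param lambda smoothness penalty (> 0), default 1e6.
#' @param ratio termination threshold on the relative weight change.
#' @param maxIter maximum reweighting iterations.
#' @return Numeric baseline vector.
#' @export
arpls <- function(x, lambda = 1e6, ratio = 1e-6, maxIter = 50L) {
  stopifnot(lambda > 0, ratio > 0)
  n <- length(x)
  P <- .d2Penalty(n, lambda)
  w <- rep(1, n)
  z <- x
  for (i in seq_len(maxIter)) {
    W <- Matrix::Diagonal(n, w)
    z <- as.numeric(Matrix::solve(W + P, w * x))
    d <- x - z
    dn <- d[d < 0]
    if (length(dn) < 2) break
    m <- mean(dn); s <- stats::sd(dn)
    if (!is.finite(s) || s == 0) break
    wNew <- 1 / (1 + exp(2 * (d - (2 * s - m)) / s))
    if (sqrt(sum((w - wNew)^2)) / sqrt(sum(w^2)) < ratio) { w <- wNew; break }
    w <- wNew
  }
  z
}

#' Options for baseline correction
#'
#' @param method one of `"none"`, `"rubberband"`, `"concave_rubberband"`,
#'   `"asls"`, `"arpls"`.
#' @param lambda smoothness penalty for asls/arpls.
#' @param p asymmetry for asls.
#' @param ratio termination ratio for arpls.
#' @param iterations iterations for the concave rubberband.
#' @return A named list of class `"BaselineOptions"`.
#' @export
baselineOptions <- function(method = c("none", "rubberband",
                                       "concave_rubberband", "asls", "arpls"),
                            lambda = 1e6, p = 0.01, ratio = 1e-6,
                            iterations = 10L) {
  method <- match.arg(method)
  stopifnot(lambda > 0, p > 0, p < 1)
  structure(list(method = method, lambda = lambda, p = p, ratio = ratio,
                 iterations = as.integer(iterations)),
            class = "BaselineOptions")
}

#' Subtract a baseline from every spectrum of an image
#'
#' Baselines are computed on the wavenumber range actually present (no
#' extrapolation) and the method with its parameters is recorded in the
#' image's provenance log.
#'
#' @param img a [HyperImage-class].
#' @param opts a [baselineOptions()] list.
#' @return A baseline-corrected [HyperImage-class].
#' @export
subtractBaseline <- function(img, opts = baselineOptions("rubberband")) {
  stopifnot(is(img, "HyperImage"), inherits(opts, "BaselineOptions"))
  if (opts$method == "none") return(img)
  X <- img@spectra
  grid <- img@wavenumber
  for (i in seq_len(nrow(X))) {
    b <- switch(opts$method,
      rubberband = rubberband(X[i, ], grid),
      concave_rubberband = concaveRubberband(X[i, ], grid,
                                             iterations = opts$iterations),
      asls = asls(X[i, ], lambda = opts$lambda, p = opts$p),
      arpls = arpls(X[i, ], lambda = opts$lambda, ratio = opts$ratio))
    X[i, ] <- X[i, ] - b
  }
  HyperImage(X, grid, dims = img@dims,
             log = c(img@log,
                     sprintf("baseline %s (lambda=%g, p=%g)", opts$method,
                             opts$lambda, opts$p)))
}
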