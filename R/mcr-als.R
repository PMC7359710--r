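# --- fast combinatorial NNLS ------------------------------------------------

# Solve the grouped normal equations K[vars, col] for every unique passive set.
.cssls <- function(AtA, AtB, Pset = NULL) {
  K <- matrix(0, nrow(AtB), ncol(AtB))
  solveSafe <- function(M, b)
    tryCatch(solve(M, b), error = function(e) qr.solve(M, b))
  if (is.null(Pset)) return(solveSafe(AtA, AtB))
  codes <- apply(Pset, 2L, function(p) paste(which(p), collapse = ","))
  for (code in unique(codes)) {
    cols <- which(codes == code)
    vars <- Pset[, cols[1L]]
    if (!any(vars)) next
    K[vars, cols] <- solveSafe(AtA[vars, vars, drop = FALSE],
                               AtB[vars, cols, drop = FALSE])
  }
  K
}

# Fast combinatorial non-negative least squares: min ||A X - B||_F, X >= 0,
# solved for all right-hand sides at once by grouping identical passive sets
# (active-set method with vectorized Lawson-Hanson inner loop).
.fcnnls <- function(A, B) {
  A <- as.matrix(A); B <- as.matrix(B)
  k <- ncol(A); n <- ncol(B)
  AtA <- crossprod(A); AtB <- crossprod(A, B)
  tol <- 10 * .Machine$double.eps * max(abs(AtA)) * k
  X <- .cssls(AtA, AtB)
  P <- X > 0
  X[!P] <- 0
  D <- X
  Fset <- which(vapply(seq_len(n), function(j) any(!P[, j]) || any(X[, j] < 0),
                       TRUE))
  W <- matrix(0, k, n)
  maxIter <- 30L * k
  iterOuter <- 0L
  while (length(Fset) && iterOuter < maxIter) {
    iterOuter <- iterOuter + 1L
    X[, Fset] <- .cssls(AtA, AtB[, Fset, drop = FALSE],
                        P[, Fset, drop = FALSE])
    Hset <- Fset[vapply(Fset, function(j) any(X[, j] < -tol), TRUE)]
    iterInner <- 0L
    while (length(Hset) && iterInner < maxIter) {
      iterInner <- iterInner + 1L
      for (j in Hset) {
        idx <- which(X[, j] < -tol & P[, j])
        if (!length(idx)) { P[X[, j] < 0, j] <- FALSE; next }
        alpha <- min(D[idx, j] / (D[idx, j] - X[idx, j]))
        D[, j] <- D[, j] - alpha * (D[, j] - X[, j])
        P[D[, j] < tol & P[, j], j] <- FALSE
      }
      X[, Hset] <- .cssls(AtA, AtB[, Hset, drop = FALSE],
                          P[, Hset, drop = FALSE])
      Hset <- Hset[vapply(Hset, function(j) any(X[, j] < -tol), TRUE)]
    }
    D[, Fset] <- pmax(X[, Fset, drop = FALSE], 0)
    W[, Fset] <- AtB[, Fset, drop = FALSE] - AtA %*% X[, Fset, drop = FALSE]
    solved <- vapply(Fset, function(j) {
      free <- !P[, j]
      !any(free) || all(W[free, j] <= tol)
    }, TRUE)
    newF <- Fset[!solved]
    for (j in newF) {
      cand <- which(!P[, j])
      P[cand[which.max(W[cand, j])], j] <- TRUE
    }
    Fset <- newF
  }
  X[X < 0] <- 0
  X
}

# --- SVD guide and SIMPLISMA ------------------------------------------------

#' Singular values of a data matrix
#'
#' Descending singular values, used to judge how many components capture the
#' variability of an image before running MCR-ALS.
#'
#' @param D numeric matrix (pixels x wavenumbers).
#' @return Numeric vector of singular values, descending.
#' @export
svdGuide <- function(D) {
  svd(as.matrix(D), nu = 0, nv = 0)$d
}

#' SIMPLISMA pure-variable selection
#'
#' Selects the k "purest" variables of a matrix by the purity criterion
#' `p = sigma / (mu + alpha * max(mu))`, deflating previously selected
#' directions through determinants of the correlation-around-origin matrix of
#' the candidate variable and the already-selected ones. Variables are the
#' columns of `D` (`axis = "columns"`) or its rows (`axis = "rows"`).
#'
#' For a pixels x wavenumbers image matrix, pure rows are the spectra of the
#' purest pixels (initial S for MCR-ALS) and pure columns are the
#' concentration maps at the purest wavenumbers (initial C).
#'
#' @param D numeric data matrix, preferably non-negative (a warning is
#'   issued otherwise).
#' @param k number of pure variables, `1 <= k <= min(dim(D))`.
#' @param alpha noise offset as a percentage of the maximum mean (default 5).
#' @param axis select pure `"columns"` or pure `"rows"`.
#' @return List with `indices` (selected variable positions along the chosen
#'   axis) and `profiles` (matrix whose columns are the selected variables'
#'   profiles over the other axis).
#' @export
simplisma <- function(D, k, alpha = 5, axis = c("columns", "rows")) {
  axis <- match.arg(axis)
  D <- as.matrix(D)
  if (any(D < 0)) warning("SIMPLISMA assumes non-negative data")
  M <- if (axis == "columns") D else t(D)
  if (k < 1 || k > min(dim(M)))
    stop("k must lie between 1 and min(dim(D))")
  nr <- nrow(M)
  mu <- colMeans(M)
  sg <- sqrt(pmax(colMeans(M^2) - mu^2, 0))
  f <- alpha / 100 * max(mu)
  basePurity <- sg / (mu + f)
  len <- sqrt(mu^2 + (sg + f)^2)
  len[len == 0] <- 1
  Mn <- sweep(M, 2L, len, "/")
  COO <- crossprod(Mn) / nr
  sel <- integer(0)
  for (i in seq_len(k)) {
    w <- vapply(seq_len(ncol(M)), function(j) {
      if (j %in% sel) return(0)
      det(COO[c(j, sel), c(j, sel), drop = FALSE])
    }, 0)
    p <- w * basePurity
    if (max(p) <= 0)
      stop(sprintf("SIMPLISMA found only %d independent variables (k = %d exceeds numerical rank)",
                   i - 1L, k))
    sel <- c(sel, which.max(p))
  }
  list(indices = sel, profiles = M[, sel, drop = FALSE])
}

# --- ROI --------------------------------------------------------------------

#' Region-of-interest mask from a polygon
#'
#' A pixel is included iff its center lies inside the polygon under the
#' even-odd rule. Vertices are given in pixel coordinates `(x = column,
#' y = row)`, 1-based; pixel centers sit at integer coordinates.
#'
#' @param poly numeric matrix or data.frame of vertices, columns `(x, y)`,
#'   at least 3 rows, not all collinear.
#' @param dims image geometry `c(height, width)`.
#' @return Logical vector of length `height * width` (row-major by pixel:
#'   pixel index = (row - 1) * width + column).
#' @export
roiMask <- function(poly, dims) {
  poly <- as.matrix(poly)
  stopifnot(ncol(poly) == 2, !anyNA(dims))
  if (nrow(poly) < 3) stop("ROI polygon needs at least 3 vertices")
  vx <- poly[, 1]; vy <- poly[, 2]
  # degenerate (collinear) polygons enclose no area
  area <- abs(sum(vx * c(vy[-1], vy[1]) - c(vx[-1], vx[1]) * vy)) / 2
  if (area < .Machine$double.eps * max(abs(poly), 1))
    stop("degenerate (collinear) ROI polygon")
  h <- dims[1]; w <- dims[2]
  px <- rep(seq_len(w), times = h)
  py <- rep(seq_len(h), each = w)
  inside <- rep(FALSE, h * w)
  n <- length(vx)
  j <- n
  for (i in seq_len(n)) {
    crosses <- ((vy[i] > py) != (vy[j] > py)) &
      (px < (vx[j] - vx[i]) * (py - vy[i]) / (vy[j] - vy[i]) + vx[i])
    inside <- xor(inside, crosses)
    j <- i
  }
  if (!any(inside)) stop("ROI polygon selects no pixels")
  inside
}

#' Apply an ROI polygon to an image
#'
#' Composes the spectra of the selected pixels into a new data matrix,
#' returning the index map needed to re-embed results into the full image.
#'
#' @param img a [HyperImage-class] with known geometry.
#' @param poly polygon vertices as for [roiMask()].
#' @return List with `matrix` (selected spectra), `mask` (logical, full
#'   image) and `indices` (positions of selected pixels).
#' @export
applyRoi <- function(img, poly) {
  stopifnot(is(img, "HyperImage"))
  if (anyNA(img@dims)) stop("applyRoi requires image geometry")
  mask <- roiMask(poly, img@dims)
  list(matrix = img@spectra[mask, , drop = FALSE], mask = mask,
       indices = which(mask))
}

# --- MCR-ALS ----------------------------------------------------------------

#' MCR-ALS configuration
#'
#' @param k number of components (>= 1).
#' @param initOn `"spectra"` (SIMPLISMA on pixel rows, initial S) or
#'   `"concentrations"` (SIMPLISMA on wavenumber columns, initial C).
#' @param simplismaAlpha SIMPLISMA noise offset percentage.
#' @param maxIter iteration cap (default 700).
#' @param relTol stop when the relative improvement of the residual error per
#'   iteration drops below this percentage (default 0.1).
#' @param seed integer seed recorded with the result.
#' @return A named list of class `"MCRConfig"`.
#' @export
mcrConfig <- function(k, initOn = c("spectra", "concentrations"),
                      simplismaAlpha = 5, maxIter = 700L, relTol = 0.1,
                      seed = 1L) {
  initOn <- match.arg(initOn)
  stopifnot(k >= 1, relTol > 0, maxIter >= 1)
  structure(list(k = as.integer(k), initOn = initOn,
                 simplismaAlpha = simplismaAlpha,
                 maxIter = as.integer(maxIter), relTol = relTol,
                 seed = as.integer(seed)),
            class = "MCRConfig")
}

#' MCR-ALS decomposition
#'
#' Decomposes `D ~ C %*% t(S')` (pixels x wavenumbers) into non-negative
#' concentrations `C` and spectra `S` by alternating non-negative least
#' squares, initialized by SIMPLISMA. The residual metric is the relative
#' Frobenius reconstruction error `||D - C S|| / ||D||` in percent, recorded
#' after every full iteration. Iteration stops when the relative improvement
#' per iteration falls below `relTol` percent, at `maxIter`, or when the
#' error increases (in which case the best factors seen are returned). A
#' component collapsing to zero is re-initialized from the pixel with the
#' largest residual, with a warning.
#'
#' @param D numeric matrix (pixels x wavenumbers) or a [HyperImage-class].
#' @param cfg an [mcrConfig()] list.
#' @param roi optional logical mask (or polygon vertex matrix, for a
#'   [HyperImage-class] input with geometry) restricting the decomposition
#'   to a subset of pixels.
#' @return An [MCRResult-class].
#' @export
mcrAls <- function(D, cfg, roi = NULL) {
  stopifnot(inherits(cfg, "MCRConfig"))
  dims <- c(NA_integer_, NA_integer_)
  if (is(D, "HyperImage")) {
    dims <- D@dims
    if (!is.null(roi) && !is.logical(roi)) roi <- roiMask(roi, D@dims)
    D <- D@spectra
  }
  D <- as.matrix(D)
  if (is.null(roi)) roi <- rep(TRUE, nrow(D))
  stopifnot(length(roi) == nrow(D))
  Dw <- D[roi, , drop = FALSE]
  if (!all(is.finite(Dw))) stop("data matrix must be finite")
  k <- cfg$k
  normD <- sqrt(sum(Dw^2))

  if (cfg$initOn == "spectra") {
    S <- t(simplisma(Dw, k, alpha = cfg$simplismaAlpha, axis = "rows")$profiles)
    C <- NULL
  } else {
    C <- simplisma(Dw, k, alpha = cfg$simplismaAlpha, axis = "columns")$profiles
    S <- .fcnnls(C, Dw)      # k x wavenumbers
  }

  history <- numeric(0)
  best <- NULL
  bestErr <- Inf
  stopReason <- "max_iter"
  for (iter in seq_len(cfg$maxIter)) {
    # C given S
    C <- t(.fcnnls(t(S), t(Dw)))
    dead <- which(colSums(C) == 0 | rowSums(S) == 0)
    if (length(dead)) {
      warning(sprintf("re-initializing %d collapsed component(s) at iteration %d",
                      length(dead), iter))
      R <- Dw - C %*% S
      for (j in dead) {
        p <- which.max(rowSums(R^2))
        S[j, ] <- pmax(R[p, ], 0)
        if (all(S[j, ] == 0)) S[j, ] <- pmax(Dw[p, ], 0)
        C[p, j] <- 1
      }
    }
    # S given C
    S <- .fcnnls(C, Dw)
    err <- sqrt(sum((Dw - C %*% S)^2)) / normD * 100
    history <- c(history, err)
    if (err < bestErr) {
      bestErr <- err
      best <- list(C = C, S = S)
    }
    if (iter > 1) {
      prev <- history[iter - 1L]
      if (err > prev) { stopReason <- "error_increase"; break }
      if (prev > 0 && (prev - err) / prev * 100 < cfg$relTol) {
        stopReason <- "tol"; break
      }
      if (prev == 0) { stopReason <- "tol"; break }
    }
  }
  new("MCRResult", conc = best$C, spec = best$S, residuals = history,
      stopReason = stopReason, roi = roi,
      config = unclass(cfg))
}
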