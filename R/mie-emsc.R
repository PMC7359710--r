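#' Kramers-Kronig transform via the Hilbert transform
#'
#' Computes the fluctuating real part of the refractive index from its
#' imaginary part (here, a normalized absorbance spectrum) as the discrete
#' Hilbert transform, evaluated with the FFT. The sign convention makes an
#' absorption peak produce the canonical dispersive (derivative-like)
#' lineshape; equivalently, `sin -> -cos`. The signal is padded at both ends
#' by an even reflection tapered to zero (cosine fade) before the FFT, which
#' suppresses both wrap-around artifacts and the spurious contribution of
#' the mirrored copies.
#'
#' @param nim numeric vector (imaginary part) on a uniform wavenumber grid.
#' @param grid the wavenumber grid; must be uniformly spaced (resample
#'   first if not).
#' @return Numeric vector `nkk`, same length as `nim`.
#' @export
kramersKronig <- function(nim, grid = NULL) {
  stopifnot(all(is.finite(nim)))
  if (!is.null(grid)) {
    s <- diff(grid)
    if (length(s) && (max(s) - min(s)) > 1e-6 * stats::median(s))
      stop("kramersKronig requires a uniform grid; resample the spectrum first")
  }
  n <- length(nim)
  if (n < 2) return(rep(0, n))
  fade <- 0.5 * (1 + cos(pi * seq_len(n) / n))   # 1 at the joint, 0 far away
  xp <- c(rev(nim) * rev(fade), nim, rev(nim) * fade)
  m <- length(xp)
  h <- numeric(m)
  if (m %% 2 == 0) {
    h[1] <- 1; h[m / 2 + 1] <- 1; h[2:(m / 2)] <- 2
  } else {
    h[1] <- 1; h[2:((m + 1) / 2)] <- 2
  }
  analytic <- stats::fft(stats::fft(xp) * h, inverse = TRUE) / m
  Im(analytic)[(n + 1):(2 * n)]
}

# van de Hulst apparent-absorbance extinction efficiency.
# Q(rho, tan beta) = 2 - 4 e^{-rho tanb} [ (cosb/rho) sin(rho-b)
#                    + (cosb/rho)^2 cos(rho-2b) ] + 4 (cosb/rho)^2 cos(2b)
# reduces at beta = 0 to 2 - (4/rho) sin rho + (4/rho^2)(1 - cos rho),
# with the analytic small-particle limit Q -> 0 as rho -> 0.
.vdhQ <- function(rho, tanb = 0) {
  Q <- numeric(length(rho))
  ok <- is.finite(rho) & rho > 1e-8
  r <- rho[ok]
  if (length(tanb) > 1) tanb <- tanb[ok]
  b <- atan(tanb)
  cb <- cos(b)
  Q[ok] <- 2 - 4 * exp(-r * tanb) *
    (cb / r * sin(r - b) + (cb / r)^2 * cos(r - 2 * b)) +
    4 * (cb / r)^2 * cos(2 * b)
  Q
}

#' Extinction-curve parameter grids
#'
#' Defines the dictionary of van de Hulst extinction curves. Two
#' parameterizations are supported: `"bassan3"` explores three parameters
#' (refractive-index scale `a`, mixing fraction `b`, sphere diameter `d` in
#' micrometers) while `"konevskikh2"` uses the two rescaled parameters
#' `alpha0` and `gamma` with `rho = alpha0 * nu * (1 + gamma * nkk)`.
#' Grids are exposed because the optimal parameter distributions are an open
#' question; defaults give 1000 (bassan3) or 225 (konevskikh2) curves.
#'
#' @param model `"konevskikh2"` or `"bassan3"`.
#' @param a,b,d numeric grids for the bassan3 axes (`d` in micrometers).
#' @param alpha0,gamma numeric grids for the konevskikh2 axes (log-spaced by
#'   default).
#' @return A named list of class `"ExtinctionParams"` with a `points` matrix
#'   (one row per parameter combination).
#' @export
extinctionParams <- function(model = c("konevskikh2", "bassan3"),
                             a = seq(1.1, 1.5, length.out = 10),
                             b = seq(0, 1, length.out = 10),
                             d = seq(2, 8, length.out = 10),
                             alpha0 = exp(seq(log(1e-4), log(3e-3),
                                              length.out = 15)),
                             gamma = exp(seq(log(0.05), log(2),
                                             length.out = 15))) {
  model <- match.arg(model)
  pts <- if (model == "bassan3") {
    stopifnot(all(a > 0), all(b >= 0), all(d > 0))
    as.matrix(expand.grid(a = a, b = b, d = d))
  } else {
    stopifnot(all(alpha0 > 0), all(gamma > 0))
    as.matrix(expand.grid(alpha0 = alpha0, gamma = gamma))
  }
  structure(list(model = model, points = pts), class = "ExtinctionParams")
}

#' Evaluate one van de Hulst extinction curve
#'
#' Computes the apparent-absorbance extinction efficiency Q over the grid for
#' one parameter point, with the resonant refractive-index fluctuation `nkk`
#' (from [kramersKronig()] of the normalized reference) entering through the
#' phase-shift parameter rho. For `"bassan3"`,
#' `rho = 2 pi d nu (a - 1 + b nkk)` (`d` converted from micrometers); for
#' `"konevskikh2"`, `rho = alpha0 * nu * (1 + gamma * nkk)`. Points where
#' rho <= 0 take the analytic small-particle limit Q = 0.
#'
#' @param point named numeric parameter point (`a`,`b`,`d` or
#'   `alpha0`,`gamma`).
#' @param nkk numeric Kramers-Kronig vector on the grid.
#' @param grid wavenumber vector (cm^-1).
#' @param model `"konevskikh2"` or `"bassan3"`.
#' @return Numeric vector Q, one value per grid point; finite and real.
#' @export
extinctionCurve <- function(point, nkk, grid,
                            model = c("konevskikh2", "bassan3")) {
  model <- match.arg(model)
  rho <- if (model == "bassan3") {
    2 * pi * (point[["d"]] * 1e-4) * grid * (point[["a"]] - 1 + point[["b"]] * nkk)
  } else {
    point[["alpha0"]] * grid * (1 + point[["gamma"]] * nkk)
  }
  .vdhQ(pmax(rho, 0))
}

#' Build an extinction dictionary
#'
#' One extinction curve per parameter-grid point, generated from the
#' reference spectrum's Kramers-Kronig transform (resonant coupling between
#' absorption and refraction).
#'
#' @param zref numeric reference spectrum on the image grid (it is min
#'   subtracted and normalized internally before the KK transform).
#' @param params an [extinctionParams()] object.
#' @param grid wavenumber vector.
#' @return Matrix `n_curves x n_wavenumbers`.
#' @export
buildDictionary <- function(zref, params, grid) {
  stopifnot(inherits(params, "ExtinctionParams"))
  nim <- zref - min(zref)
  mx <- max(nim)
  if (mx > 0) nim <- nim / mx
  nkk <- kramersKronig(nim, grid)
  pts <- params$points
  D <- matrix(0, nrow(pts), length(grid))
  for (i in seq_len(nrow(pts)))
    D[i, ] <- extinctionCurve(pts[i, ], nkk, grid, model = params$model)
  D
}

#' Compress an extinction dictionary to PCA loadings
#'
#' Each dictionary row is first orthogonalized against the subspace spanned
#' by the constant, (optionally) the linear wavenumber term and the reference
#' spectrum, so the scattering loadings cannot absorb what the main EMSC
#' terms describe. PCA is then run on the orthogonalized rows without
#' variance normalization and the top-N loadings returned; they are mutually
#' orthonormal and orthogonal to the removed subspace.
#'
#' @param D dictionary matrix (curves x wavenumbers).
#' @param zref reference spectrum on the grid.
#' @param N number of loadings to keep.
#' @param includeLinear logical, include the linear wavenumber term in the
#'   removed subspace.
#' @param grid wavenumber vector.
#' @return Matrix `n_wavenumbers x N` of loading vectors (columns). If the
#'   orthogonalized dictionary has rank below N, rank-many loadings are
#'   returned with a warning.
#' @export
compressDictionary <- function(D, zref, N, includeLinear = TRUE, grid) {
  B <- cbind(1, if (includeLinear) grid, zref)
  QB <- qr.Q(qr(B))
  Dorth <- D - (D %*% QB) %*% t(QB)
  sv <- svd(Dorth, nu = 0)
  tol <- max(dim(Dorth)) * .Machine$double.eps * sv$d[1]
  rk <- sum(sv$d > max(tol, 1e-12 * max(sv$d[1], 1)))
  if (N > rk) {
    warning(sprintf("requested %d loadings but dictionary rank is %d", N, rk))
    N <- rk
  }
  sv$v[, seq_len(N), drop = FALSE]
}

# Batch EMSC least-squares fit.
# Z: pixels x wavenumbers; B: wavenumbers x q shared design (1, nu?, loadings);
# R: pixels x wavenumbers per-pixel reference (or a single vector recycled).
.emscFitBatch <- function(Z, B, R, rescaleByH = TRUE) {
  if (is.null(dim(R))) R <- matrix(R, nrow(Z), length(R), byrow = TRUE)
  q <- ncol(B)
  BtB <- crossprod(B)
  ZB <- Z %*% B
  RB <- R %*% B
  rr <- rowSums(R * R)
  rz <- rowSums(R * Z)
  np <- nrow(Z)
  coefs <- matrix(0, np, q)
  h <- numeric(np)
  M <- matrix(0, q + 1, q + 1)
  M[seq_len(q), seq_len(q)] <- BtB
  for (p in seq_len(np)) {
    M[q + 1, seq_len(q)] <- RB[p, ]
    M[seq_len(q), q + 1] <- RB[p, ]
    M[q + 1, q + 1] <- rr[p]
    beta <- tryCatch(solve(M, c(ZB[p, ], rz[p])),
                     error = function(e) qr.solve(M, c(ZB[p, ], rz[p])))
    coefs[p, ] <- beta[seq_len(q)]
    h[p] <- beta[q + 1]
  }
  E <- Z - coefs %*% t(B) - R * h
  Zcorr <- R + E
  if (rescaleByH) {
    degenerate <- abs(h) < 1e-8
    if (any(degenerate))
      warning(sprintf("|h| < 1e-8 for %d pixel(s); those are left unrescaled",
                      sum(degenerate)))
    hh <- ifelse(degenerate, 1, h)
    Zcorr <- Zcorr / hh
  }
  list(coefs = coefs, h = h, residual = E, Zcorr = Zcorr)
}

#' EMSC model and least-squares fit
#'
#' `emscModel()` assembles the EMSC design for a reference spectrum:
#' constant, optional linear wavenumber term, the reference itself, and N
#' scattering loadings from the compressed extinction dictionary.
#' `emscFit()` fits one observed spectrum by ordinary least squares,
#' `Zraw = c + m nu + h Zref + sum_i g_i p_i + eps`, and returns the
#' corrected spectrum `Zcorr = Zref + eps`, or `(Zref + eps) / h` when
#' `rescaleByH` is on (with a fallback to unrescaled when `|h| < 1e-8`).
#'
#' @param zref numeric reference spectrum on the image grid.
#' @param grid wavenumber vector.
#' @param params an [extinctionParams()] object.
#' @param N number of scattering loadings (defaults: 7 for konevskikh2,
#'   8 for bassan3).
#' @param includeLinear logical, include the `m nu` term.
#' @return `emscModel()`: list of class `"EMSCModel"` with elements `zref`,
#'   `grid`, `loadings`, `includeLinear`. `emscFit()`: list of class
#'   `"EMSCFit"` with coefficients `c`, `m`, `h`, `g`, the residual `eps`,
#'   the fitted spectrum and `Zcorr`.
#' @export
emscModel <- function(zref, grid, params = extinctionParams(),
                      N = if (params$model == "bassan3") 8L else 7L,
                      includeLinear = TRUE) {
  D <- buildDictionary(zref, params, grid)
  P <- compressDictionary(D, zref, N, includeLinear = includeLinear,
                          grid = grid)
  structure(list(zref = zref, grid = grid, loadings = P,
                 includeLinear = includeLinear),
            class = "EMSCModel")
}

#' @rdname emscModel
#' @param Zraw numeric observed spectrum on the model grid.
#' @param model an `"EMSCModel"` from [emscModel()].
#' @param rescaleByH logical, divide the corrected spectrum by `h`.
#' @export
emscFit <- function(Zraw, model, rescaleByH = TRUE) {
  stopifnot(inherits(model, "EMSCModel"),
            length(Zraw) == length(model$zref))
  B <- cbind(1, if (model$includeLinear) model$grid, model$loadings)
  res <- .emscFitBatch(matrix(Zraw, 1L), B, model$zref,
                       rescaleByH = rescaleByH)
  co <- res$coefs[1L, ]
  structure(list(
    c = co[1],
    m = if (model$includeLinear) co[2] else 0,
    h = res$h[1L],
    g = co[(1 + as.integer(model$includeLinear) + 1):length(co)],
    eps = res$residual[1L, ],
    fitted = Zraw - res$residual[1L, ],
    Zcorr = res$Zcorr[1L, ]), class = "EMSCFit")
}

# Min-subtract and area-normalize a reference spectrum.
.normRef <- function(v, grid) {
  vm <- v - min(v)
  A <- pracma::trapz(grid, vm)
  if (!is.finite(A) || A <= 0)
    stop("degenerate (flat) reference spectrum")
  # area-normalized, rescaled by the grid span so values are O(1)
  vm / A * (max(grid) - min(grid))
}

# As .normRef but degenerate (flat) inputs are returned unchanged, for
# per-pixel references inside the CRMieSC loop.
.normRefSafe <- function(v, grid) {
  tryCatch(.normRef(v, grid), error = function(e) v)
}

# Seeded k-means wrapper with fallbacks for degenerate starts.
.seededKmeans <- function(X, k, seed, nstart = 10L) {
  k <- min(k, nrow(unique(X)))
  set.seed(seed)
  res <- tryCatch(
    stats::kmeans(X, centers = k, nstart = nstart, iter.max = 100L),
    error = function(e) NULL)
  if (is.null(res)) {
    set.seed(seed + 1L)
    res <- tryCatch(
      stats::kmeans(X, centers = k, nstart = nstart, iter.max = 100L,
                    algorithm = "MacQueen"),
      error = function(e) NULL)
  }
  if (is.null(res)) {
    set.seed(seed)
    res <- stats::kmeans(X, centers = k, nstart = 1L, iter.max = 100L,
                         algorithm = "Lloyd")
  }
  res
}

#' Options for clustered resonant Mie scattering correction
#'
#' @param nClusters number of k-means clusters (default 30).
#' @param maxIterations iteration cap (default 30).
#' @param stabilize logical; prepend single-cluster iterations and finish
#'   with gradual reference updates (`Zref <- Zref/2 + Zcorr/2`) during the
#'   last quarter of the iterations (at least 2) with cluster assignments
#'   frozen.
#' @param clusteringEnabled logical; `FALSE` corrects every spectrum
#'   individually (one model per pixel).
#' @param autoStop logical; freeze a cluster when the relative change of its
#'   reference falls below `stopTol` and stop when all clusters are frozen.
#' @param rescaleByH logical; divide corrected spectra by the fitted `h`.
#' @param extinction an [extinctionParams()] object.
#' @param N number of PCA scattering loadings.
#' @param includeLinear logical, include the linear wavenumber EMSC term.
#' @param stabilizeIterations number of initial single-cluster iterations.
#' @param stopTol relative reference-change tolerance for `autoStop`.
#' @param seed integer seed for the clustering.
#' @param kmRestarts k-means restarts inside the iteration loop.
#' @return A named list of class `"CRMieSCOptions"`.
#' @export
crmiescOptions <- function(nClusters = 30L, maxIterations = 30L,
                           stabilize = TRUE, clusteringEnabled = TRUE,
                           autoStop = TRUE, rescaleByH = TRUE,
                           extinction = extinctionParams(),
                           N = if (extinction$model == "bassan3") 8L else 7L,
                           includeLinear = TRUE,
                           stabilizeIterations = 2L, stopTol = 1e-4,
                           seed = 1L, kmRestarts = 3L) {
  stopifnot(nClusters >= 1, maxIterations >= 1)
  structure(list(nClusters = as.integer(nClusters),
                 maxIterations = as.integer(maxIterations),
                 stabilize = stabilize, clusteringEnabled = clusteringEnabled,
                 autoStop = autoStop, rescaleByH = rescaleByH,
                 extinction = extinction, N = as.integer(N),
                 includeLinear = includeLinear,
                 stabilizeIterations = as.integer(stabilizeIterations),
                 stopTol = stopTol, seed = as.integer(seed),
                 kmRestarts = as.integer(kmRestarts)),
            class = "CRMieSCOptions")
}

#' Clustered resonant Mie scattering correction (CRMieSC)
#'
#' Iterative EMSC-based scattering correction sharing dictionary models
#' across clusters of similar spectra. The first iteration uses the initial
#' reference for all pixels and is computed once. Each subsequent iteration
#' re-clusters the current corrected spectra by k-means (clusters may
#' initially reflect scattering rather than chemistry), builds and
#' compresses one extinction dictionary per cluster from the cluster mean,
#' and fits every member spectrum with the cluster-level loadings but its own
#' current reference (its previous corrected spectrum). With `stabilize`,
#' initial iterations use a single cluster and the final iterations freeze
#' cluster assignments, updating references only gradually
#' (`Zref(n+1) = Zref(n)/2 + Zcorr(n)/2`). With `autoStop`, a cluster whose
#' reference changes by less than `stopTol` (relative L2) is frozen.
#' Corrected spectra are returned raw (no non-negativity clipping).
#'
#' References are min-subtracted and area-normalized before each dictionary
#' generation, which makes the result invariant to the initial scaling of the
#' reference spectrum (the two-parameter extinction model is otherwise
#' nonlinear in that scale).
#'
#' @param img a [HyperImage-class].
#' @param ref0 a [ReferenceSpectrum-class] initial reference (interpolated
#'   onto the image grid).
#' @param opts a [crmiescOptions()] list.
#' @return List with `image` (corrected [HyperImage-class]), `h` (pixels x 1
#'   final multiplicative coefficients), `clusterRefs` (list, per iteration,
#'   of cluster-reference matrices), `assignments` (final cluster ids),
#'   `iterations` (number executed) and `converged`.
#' @export
crmiesc <- function(img, ref0, opts = crmiescOptions()) {
  stopifnot(is(img, "HyperImage"), is(ref0, "ReferenceSpectrum"),
            inherits(opts, "CRMieSCOptions"))
  grid <- img@wavenumber
  Z <- img@spectra
  np <- nrow(Z)
  r0 <- interpolateToGrid(ref0, grid)
  if (all(r0 == 0))
    stop("initial reference does not overlap the image grid")
  zr0 <- .normRef(r0, grid)

  nClus <- opts$nClusters
  if (opts$clusteringEnabled && nClus > np) {
    warning(sprintf("nClusters reduced from %d to number of pixels (%d)",
                    nClus, np))
    nClus <- np
  }
  nGrad <- if (opts$stabilize) max(2L, ceiling(0.25 * opts$maxIterations)) else 0L
  nStab <- if (opts$stabilize) opts$stabilizeIterations else 0L
  # iteration index after which the gradual-update phase begins; auto-stop
  # may pull it forward when the corrected spectra stop improving
  gradEntry <- opts$maxIterations - nGrad
  relHist <- numeric(0)

  # iteration 1: shared model from the initial reference, computed once
  model <- emscModel(zr0, grid, params = opts$extinction, N = opts$N,
                     includeLinear = opts$includeLinear)
  B <- cbind(1, if (opts$includeLinear) grid, model$loadings)
  fit <- .emscFitBatch(Z, B, zr0, rescaleByH = opts$rescaleByH)
  Zc <- fit$Zcorr
  h <- fit$h
  refHistory <- list(matrix(zr0, 1L))
  assign <- rep(1L, np)
  prevRefs <- matrix(zr0, 1L)
  frozen <- logical(1L)
  it <- 1L
  converged <- FALSE

  while (it < opts$maxIterations) {
    it <- it + 1L
    gradual <- opts$stabilize && it > gradEntry
    reclustered <- FALSE
    if (!opts$clusteringEnabled && it > 1L + nStab) {
      if (!identical(assign, seq_len(np))) {
        assign <- seq_len(np); reclustered <- TRUE
      }
    } else if (!gradual) {
      kIt <- if (it <= 1L + nStab) 1L else nClus
      newAssign <- if (kIt == 1L) rep(1L, np) else
        .seededKmeans(Zc, kIt, seed = opts$seed + it,
                      nstart = opts$kmRestarts)$cluster
      if (!identical(newAssign, assign)) reclustered <- TRUE
      assign <- newAssign
    } # gradual phase: keep previous assignments
    kIt <- max(assign)
    newRefs <- matrix(0, kIt, ncol(Z))
    # per-cluster freezing is meaningful only while assignments are stable
    if (reclustered || length(frozen) != kIt) frozen <- logical(kIt)
    refsComparable <- !reclustered && nrow(prevRefs) == kIt
    changed <- FALSE
    Zprev <- Zc
    for (cl in seq_len(kIt)) {
      mem <- which(assign == cl)
      if (!length(mem)) { frozen[cl] <- TRUE; next }
      if (frozen[cl]) { newRefs[cl, ] <- prevRefs[cl, ]; next }
      target <- .normRefSafe(colMeans(Zc[mem, , drop = FALSE]), grid)
      refCl <- if (gradual && refsComparable)
        0.5 * prevRefs[cl, ] + 0.5 * target else target
      newRefs[cl, ] <- refCl
      if (opts$autoStop && refsComparable) {
        relChange <- sqrt(sum((refCl - prevRefs[cl, ])^2)) /
          max(sqrt(sum(prevRefs[cl, ]^2)), .Machine$double.eps)
        if (relChange < opts$stopTol) { frozen[cl] <- TRUE; next }
      }
      changed <- TRUE
      modelCl <- emscModel(refCl, grid, params = opts$extinction, N = opts$N,
                           includeLinear = opts$includeLinear)
      Bcl <- cbind(1, if (opts$includeLinear) grid, modelCl$loadings)
      Rmem <- Zc[mem, , drop = FALSE]
      Rmem <- t(apply(Rmem, 1L, function(v) .normRefSafe(v, grid)))
      if (length(mem) == 1L) Rmem <- matrix(Rmem, 1L)
      fitCl <- .emscFitBatch(Z[mem, , drop = FALSE], Bcl, Rmem,
                             rescaleByH = opts$rescaleByH)
      Zc[mem, ] <- fitCl$Zcorr
      h[mem] <- fitCl$h
    }
    prevRefs <- newRefs
    refHistory[[it]] <- newRefs
    if (opts$autoStop) {
      # relative change of the corrected spectra; the correction settles
      # within a few iterations, after which spectra drift slowly through
      # the scale ambiguity, so a plateau (change no longer decreasing)
      # counts as converged alongside the absolute tolerance
      relAll <- sqrt(sum((Zc - Zprev)^2)) / max(sqrt(sum(Zprev^2)),
                                                .Machine$double.eps)
      plateau <- relAll < opts$stopTol ||
        (it >= 6L && length(relHist) > 0 && relAll > 0.9 * min(relHist))
      relHist <- c(relHist, relAll)
      if (!changed) { converged <- TRUE; break }
      if (gradual && (relAll < opts$stopTol || it - gradEntry >= nGrad)) {
        converged <- TRUE; break
      }
      if (!gradual && plateau) {
        if (opts$stabilize) gradEntry <- min(gradEntry, it)
        else { converged <- TRUE; break }
      }
    }
  }
  out <- HyperImage(Zc, grid, dims = img@dims,
                    log = c(img@log,
                            sprintf("CRMieSC (%s, %d clusters, %d iterations)",
                                    opts$extinction$model, nClus, it)))
  list(image = out, h = h, clusterRefs = refHistory, assignments = assign,
       iterations = it, converged = converged)
}
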