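# Evaluate expr under a temporary RNG state seeded with `seed`, restoring the
# caller's stream afterwards. Each contamination draws from its own derived
# seed so toggling one does not perturb the others.
.withSeed <- function(seed, expr) {
  has <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (has) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (!is.null(old)) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed %% .Machine$integer.max)
  expr
}

#' Synthetic atmospheric reference spectrum
#'
#' A fine-structure gas reference on the conventional 900-3840 cm^-1 grid at
#' 2 cm^-1 spacing: dense narrow lines in the two water-vapor regions
#' (1300-2100 and 3410-3850 cm^-1) and a broad doublet in the CO2 region
#' (2280-2430 cm^-1). Line positions and intensities are fixed by the seed;
#' any fine-line reference works for factor fitting, so no spectroscopic
#' database is involved.
#'
#' @param grid wavenumber vector (default 900-3840 cm^-1 at 2 cm^-1).
#' @param seed integer seed fixing the line layout.
#' @return A [ReferenceSpectrum-class] labelled `"atmospheric"`.
#' @export
makeAtmosphereReference <- function(grid = seq(900, 3840, by = 2),
                                    seed = 42L) {
  .withSeed(seed, {
    v <- numeric(length(grid))
    lines <- function(lo, hi, n, wmin, wmax, amax) {
      ctr <- stats::runif(n, lo, hi)
      wd <- stats::runif(n, wmin, wmax)
      am <- stats::runif(n, 0.1, amax)
      for (i in seq_len(n))
        v <<- v + am[i] * exp(-0.5 * ((grid - ctr[i]) / wd[i])^2)
    }
    lines(1320, 2080, 120, 2, 5, 1)     # water, low region
    lines(3420, 3840, 90, 2, 6, 0.8)    # water, high region
    # CO2 asymmetric doublet
    v <- v + 1.2 * exp(-0.5 * ((grid - 2340) / 12)^2) +
      0.9 * exp(-0.5 * ((grid - 2362) / 10)^2)
    ReferenceSpectrum(grid, v, label = "atmospheric")
  })
}

#' Generate pure component spectra
#'
#' Each component is a positive sum of 3-8 Gaussian or Lorentzian bands with
#' distinct centers, mimicking mid-IR absorbance spectra (most bands in the
#' fingerprint region, some CH-stretch bands near 2800-3000 cm^-1). The
#' generator redraws components until all pairwise cosine similarities are
#' below 0.95, and is bit-reproducible from the seed.
#'
#' @param k number of components (>= 1).
#' @param grid wavenumber vector.
#' @param seed integer seed.
#' @return Matrix `k x length(grid)` of non-negative spectra.
#' @export
makePureComponents <- function(k, grid, seed = 1L) {
  stopifnot(k >= 1)
  .withSeed(seed, {
    oneComponent <- function() {
      nb <- sample(3:8, 1)
      ctr <- c(stats::runif(max(1, nb - 2), 950, 1800),
               stats::runif(min(nb, 2), 2800, 3100))[seq_len(nb)]
      wd <- stats::runif(nb, 15, 60)
      am <- stats::runif(nb, 0.2, 1)
      lor <- stats::runif(nb) < 0.3
      s <- numeric(length(grid))
      for (i in seq_len(nb)) {
        s <- s + if (lor[i])
          am[i] * wd[i]^2 / ((grid - ctr[i])^2 + wd[i]^2)
        else am[i] * exp(-0.5 * ((grid - ctr[i]) / wd[i])^2)
      }
      s
    }
    S <- matrix(0, k, length(grid))
    for (j in seq_len(k)) {
      for (try in 1:50) {
        cand <- oneComponent()
        ok <- TRUE
        if (j > 1) {
          for (i in seq_len(j - 1)) {
            cs <- sum(cand * S[i, ]) /
              (sqrt(sum(cand^2)) * sqrt(sum(S[i, ]^2)))
            if (cs >= 0.95) { ok <- FALSE; break }
          }
        }
        if (ok) { S[j, ] <- cand; break }
      }
      if (all(S[j, ] == 0))
        stop("could not generate sufficiently distinct components")
    }
    S
  })
}

#' Generate spatial concentration maps
#'
#' Produces non-negative per-pixel concentrations and region labels for one
#' of three geometries: random Gaussian `"blobs"`, vertical `"stripes"`, or
#' `"cell_on_film"` — a film background covering the image, an elliptical
#' cell body (hypha) with a chemically distinct core, and a weak halo ring
#' around the cell, mirroring the film/hypha/halo structure of fungal
#' colonization images. One near-pure pixel (purity >= 0.95) is planted per
#' component so pure-variable initialization assumptions hold.
#'
#' Pixels are ordered row-major: pixel index = (row - 1) * width + column.
#'
#' @param height,width image geometry.
#' @param k number of components.
#' @param geometry `"blobs"`, `"stripes"` or `"cell_on_film"`.
#' @param seed integer seed.
#' @return List with `C` (pixels x k), `labels` (integer region per pixel).
#' @export
makeConcentrationMaps <- function(height, width, k,
                                  geometry = c("cell_on_film", "blobs",
                                               "stripes"),
                                  seed = 1L) {
  geometry <- match.arg(geometry)
  np <- height * width
  maxReg <- switch(geometry, blobs = np, stripes = width, cell_on_film = 6L)
  if (k > maxReg)
    stop(sprintf("geometry '%s' cannot represent %d components (max %d)",
                 geometry, k, maxReg))
  col <- rep(seq_len(width), times = height)
  row <- rep(seq_len(height), each = width)
  .withSeed(seed, {
    C <- matrix(0, np, k)
    if (geometry == "blobs") {
      cx <- stats::runif(k, 1, width); cy <- stats::runif(k, 1, height)
      rad <- stats::runif(k, 0.15, 0.35) * min(height, width)
      for (j in seq_len(k))
        C[, j] <- exp(-((col - cx[j])^2 + (row - cy[j])^2) / (2 * rad[j]^2))
      labels <- max.col(C, ties.method = "first")
    } else if (geometry == "stripes") {
      edges <- round(seq(0, width, length.out = k + 1))
      labels <- findInterval(col, edges[-1], left.open = FALSE) + 1L
      labels <- pmin(labels, k)
      for (j in seq_len(k))
        C[cbind(which(labels == j), j)] <- stats::runif(sum(labels == j),
                                                        0.7, 1)
    } else { # cell_on_film
      cx <- width / 2 + stats::runif(1, -2, 2)
      cy <- height / 2 + stats::runif(1, -2, 2)
      a <- 0.28 * width; b <- 0.2 * height
      ang <- stats::runif(1, 0, pi)
      xr <- (col - cx) * cos(ang) + (row - cy) * sin(ang)
      yr <- -(col - cx) * sin(ang) + (row - cy) * cos(ang)
      r2 <- (xr / a)^2 + (yr / b)^2
      inCell <- r2 < 1
      inCore <- r2 < 0.35
      inHalo <- !inCell & r2 < 1.8
      # film thickness varies smoothly across the image; composition within
      # a region is sharp, so normalized concentrations separate regions
      # that raw intensities (dominated by thickness) do not
      thick <- 0.6 + 0.8 * (col / width) + 0.1 * sin(row / height * 2 * pi)
      C[, 1] <- 1
      if (k >= 2) C[, 2] <- 1.2 * inCell
      if (k >= 3) C[, 3] <- 0.8 * inCore
      if (k >= 4) C[, 4] <- 0.15 * inHalo   # weak halo signal
      if (k >= 5) for (j in 5:k) {
        bx <- stats::runif(1, 1, width); by <- stats::runif(1, 1, height)
        blob <- (col - bx)^2 + (row - by)^2 < (0.08 * width)^2
        C[, j] <- 0.6 * blob
      }
      jit <- matrix(1 + 0.02 * stats::rnorm(np * k), np, k)
      C <- pmax(C * jit, 0) * thick
      labels <- rep(1L, np)                       # film
      labels[inCell] <- 2L                        # hypha (cell incl. core)
      if (k >= 4) labels[inHalo] <- 3L            # halo ring
      if (k >= 5) for (j in 5:k)
        labels[C[, j] > 0.3 * thick] <- j - 1L
    }
    # plant one near-pure pixel per component (purity >= 0.95)
    for (j in seq_len(k)) {
      purity <- C[, j] / pmax(rowSums(C), .Machine$double.eps)
      p <- which.max(purity)
      if (purity[p] < 0.95) {
        peak <- max(C[, j], 0.5)
        C[p, ] <- 0.02 * peak / max(1, k - 1)
        C[p, j] <- peak
      }
    }
    list(C = C, labels = as.integer(labels))
  })
}

#' Inject atmospheric gas contamination
#'
#' Adds `a_i * r` per region to every spectrum, with an independent factor
#' per region and pixel, inverting the subtraction model of the atmospheric
#' correction.
#'
#' @param img a [HyperImage-class].
#' @param atmRef a [ReferenceSpectrum-class].
#' @param factors numeric per-region factors: a vector of length
#'   `length(regions)` (same factor for all pixels) or a pixels x regions
#'   matrix.
#' @param regions list of `c(lo, hi)` regions (defaults to the standard two
#'   water regions and the CO2 region).
#' @return List with `image` and the `factors` matrix actually applied.
#' @export
addAtmosphere <- function(img, atmRef, factors,
                          regions = list(c(1300, 2100), c(3410, 3850),
                                         c(2280, 2430))) {
  stopifnot(is(img, "HyperImage"), is(atmRef, "ReferenceSpectrum"))
  grid <- img@wavenumber
  r <- interpolateToGrid(atmRef, grid)
  np <- nrow(img@spectra)
  if (is.null(dim(factors)))
    factors <- matrix(factors, np, length(regions), byrow = TRUE)
  stopifnot(nrow(factors) == np, ncol(factors) == length(regions))
  X <- img@spectra
  for (i in seq_along(regions)) {
    idx <- .regionIdx(grid, regions[[i]])
    if (!length(idx)) next
    X[, idx] <- X[, idx, drop = FALSE] + outer(factors[, i], r[idx])
  }
  list(image = HyperImage(X, grid, dims = img@dims,
                          log = c(img@log, "synthetic atmosphere added")),
       factors = factors)
}

#' Inject resonant Mie-type distortion
#'
#' Adds, per pixel, `b * Q(nu; alpha0, gamma, nkk(true spectrum))` with the
#' extinction curve from the same [extinctionCurve()] code path used by the
#' corrector, plus an optional multiplicative scaling `h`. Parameters
#' outside the corrector's default dictionary range trigger a warning
#' (correction is then not guaranteed).
#'
#' @param img a [HyperImage-class] (the clean spectra whose refractive index
#'   drives the resonance).
#' @param alpha0,gamma,amplitude numeric per-pixel parameter vectors (length
#'   1 recycled).
#' @param hscale optional per-pixel multiplicative scaling (default 1).
#' @param params an [extinctionParams()] object defining the in-dictionary
#'   range for the warning check.
#' @return List with `image` and the recorded `params` data.frame.
#' @export
addMieDistortion <- function(img, alpha0, gamma, amplitude, hscale = 1,
                             params = extinctionParams()) {
  stopifnot(is(img, "HyperImage"), params$model == "konevskikh2")
  grid <- img@wavenumber
  np <- nrow(img@spectra)
  alpha0 <- rep_len(alpha0, np); gamma <- rep_len(gamma, np)
  amplitude <- rep_len(amplitude, np); hscale <- rep_len(hscale, np)
  rng <- apply(params$points, 2, range)
  if (any(alpha0 < rng[1, "alpha0"] | alpha0 > rng[2, "alpha0"]) ||
      any(gamma < rng[1, "gamma"] | gamma > rng[2, "gamma"]))
    warning("Mie parameters outside the corrector's dictionary range; correction not guaranteed")
  X <- img@spectra
  out <- X
  for (p in seq_len(np)) {
    nim <- X[p, ] - min(X[p, ])
    mx <- max(nim)
    if (mx > 0) nim <- nim / mx
    nkk <- kramersKronig(nim, grid)
    Q <- extinctionCurve(c(alpha0 = alpha0[p], gamma = gamma[p]), nkk, grid,
                         model = "konevskikh2")
    out[p, ] <- hscale[p] * X[p, ] + amplitude[p] * Q
  }
  list(image = HyperImage(out, grid, dims = img@dims,
                          log = c(img@log, "synthetic Mie distortion added")),
       params = data.frame(alpha0 = alpha0, gamma = gamma,
                           amplitude = amplitude, hscale = hscale))
}

#' Inject a baseline and white noise
#'
#' Adds a per-pixel baseline of the chosen shape plus i.i.d. Gaussian noise,
#' deterministically from the seed.
#'
#' @param img a [HyperImage-class].
#' @param kind `"constant"`, `"linear"`, `"poly"` or `"sigmoid"`.
#' @param amplitude baseline amplitude scale (0 disables the baseline).
#' @param sigma noise standard deviation (0 disables the noise).
#' @param seed integer seed.
#' @return List with `image`, `coefficients` (pixels x n matrix) and
#'   `sigma`.
#' @export
addBaselineNoise <- function(img, kind = c("constant", "linear", "poly",
                                           "sigmoid"),
                             amplitude = 0.1, sigma = 0.005, seed = 1L) {
  kind <- match.arg(kind)
  stopifnot(is(img, "HyperImage"))
  grid <- img@wavenumber
  t <- (grid - min(grid)) / (max(grid) - min(grid))
  np <- nrow(img@spectra)
  .withSeed(seed, {
    coefs <- switch(kind,
      constant = matrix(stats::runif(np, -1, 1) * amplitude, np, 1),
      linear = cbind(stats::runif(np, -1, 1), stats::runif(np, -1, 1)) *
        amplitude,
      poly = cbind(stats::runif(np, -1, 1), stats::runif(np, -1, 1),
                   stats::runif(np, -1, 1)) * amplitude,
      sigmoid = cbind(stats::runif(np, 0.5, 1) * amplitude,
                      stats::runif(np, 0.3, 0.7),      # center
                      stats::runif(np, 0.05, 0.2)))    # width
    base <- switch(kind,
      constant = matrix(coefs[, 1], np, length(t)),
      linear = coefs[, 1] %o% rep(1, length(t)) + coefs[, 2] %o% t,
      poly = coefs[, 1] %o% rep(1, length(t)) + coefs[, 2] %o% t +
        coefs[, 3] %o% t^2,
      sigmoid = {
        B <- matrix(0, np, length(t))
        for (p in seq_len(np))
          B[p, ] <- coefs[p, 1] / (1 + exp(-(t - coefs[p, 2]) / coefs[p, 3]))
        B
      })
    noise <- if (sigma > 0)
      matrix(stats::rnorm(np * length(t), 0, sigma), np) else 0
    list(image = HyperImage(img@spectra + base + noise, grid,
                            dims = img@dims,
                            log = c(img@log,
                                    sprintf("synthetic %s baseline + noise (sigma %g)",
                                            kind, sigma))),
         coefficients = coefs, sigma = sigma)
  })
}

#' Generate a phantom hyperspectral image with ground truth
#'
#' Assembles a complete phantom: pure component spectra, spatial
#' concentration maps, and (selectably) atmospheric contamination, resonant
#' Mie-type distortion, a smooth baseline, and white noise. Every
#' contamination draws from its own seed derived from the master seed, so
#' the whole object — including each contamination record — regenerates
#' bit-exactly from `(seed, arguments)`, and switching one contamination off
#' leaves the others unchanged.
#'
#' The default emulates the scale of typical FTIR microscopy images of
#' fungal hyphae on an organic film: 64 x 64 pixels, 900-3850 cm^-1 at
#' 2 cm^-1 (1476 points), four components in the cell-on-film geometry.
#'
#' @param seed master integer seed.
#' @param height,width image geometry.
#' @param k number of components.
#' @param geometry passed to [makeConcentrationMaps()].
#' @param grid wavenumber vector.
#' @param atmosphere logical or numeric: `FALSE` for none, `TRUE` for a
#'   spatially varying humidity field, or a length-3 numeric of fixed
#'   per-region factors (water-low, water-high, CO2).
#' @param mie logical, inject resonant Mie distortion.
#' @param baseline `"none"` or a kind for [addBaselineNoise()].
#' @param sigma noise standard deviation.
#' @param atmRef atmospheric reference used for the contamination.
#' @return A [Phantom-class].
#' @export
makePhantom <- function(seed = 1L, height = 64L, width = 64L, k = 4L,
                        geometry = "cell_on_film",
                        grid = seq(900, 3850, by = 2),
                        atmosphere = TRUE, mie = TRUE, baseline = "linear",
                        sigma = 0.005,
                        atmRef = makeAtmosphereReference()) {
  seed <- as.integer(seed)
  S <- makePureComponents(k, grid, seed = seed + 101L)
  maps <- makeConcentrationMaps(height, width, k, geometry = geometry,
                                seed = seed + 202L)
  clean <- maps$C %*% S
  img <- HyperImage(clean, grid, dims = c(height, width),
                    log = sprintf("phantom seed %d", seed))
  contamination <- list()
  if (!isFALSE(atmosphere)) {
    factors <- if (is.numeric(atmosphere)) {
      matrix(atmosphere, height * width, 3L, byrow = TRUE)
    } else {
      .withSeed(seed + 303L, {
        colg <- rep(seq_len(width), times = height)
        rowg <- rep(seq_len(height), each = width)
        humidity <- 0.7 + 0.2 * sin(colg / width * 2 * pi + stats::runif(1, 0, pi)) *
          cos(rowg / height * 2 * pi)
        jitter <- matrix(stats::rnorm(height * width * 3, 0, 0.02),
                         ncol = 3)
        scales <- c(1, 0.6, 0.8)
        sweep(humidity + jitter, 2L, scales, "*")
      })
    }
    res <- addAtmosphere(img, atmRef, factors)
    img <- res$image
    contamination$atmosphere <- list(factors = res$factors)
  }
  if (isTRUE(mie)) {
    pars <- .withSeed(seed + 404L, {
      np <- height * width
      list(alpha0 = exp(stats::runif(np, log(3e-4), log(2e-3))),
           gamma = exp(stats::runif(np, log(0.1), log(1))),
           amplitude = stats::runif(np, 0.1, 0.4),
           hscale = stats::runif(np, 0.9, 1.1))
    })
    # resonance driven by the clean (true) spectra
    cleanImg <- HyperImage(clean, grid, dims = c(height, width))
    res <- addMieDistortion(cleanImg, pars$alpha0, pars$gamma,
                            pars$amplitude, pars$hscale)
    # distortion = distorted clean minus clean; add onto current image
    img <- HyperImage(img@spectra + (res$image@spectra - clean), grid,
                      dims = c(height, width),
                      log = c(img@log, "synthetic Mie distortion added"))
    contamination$mie <- res$params
  }
  if (!identical(baseline, "none") || sigma > 0) {
    res <- addBaselineNoise(img,
                            kind = if (identical(baseline, "none"))
                              "constant" else baseline,
                            amplitude = if (identical(baseline, "none"))
                              0 else 0.1,
                            sigma = sigma, seed = seed + 505L)
    img <- res$image
    contamination$baseline <- list(kind = baseline,
                                   coefficients = res$coefficients,
                                   sigma = sigma)
  }
  new("Phantom", image = img, trueC = maps$C, trueS = S,
      labels = maps$labels, contamination = contamination, seed = seed)
}
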