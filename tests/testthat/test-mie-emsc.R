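test_that("Kramers-Kronig transform matches analytic Hilbert pairs", {
  expect_equal(kramersKronig(rep(0, 100)), rep(0, 100))
  # sin -> -cos on a long grid, interior points within 2%
  t <- seq(0, 100 * pi, length.out = 4096)
  nkk <- kramersKronig(sin(t))
  interior <- 500:3596
  expect_lt(max(abs(nkk[interior] + cos(t[interior]))), 0.02)
  # Lorentzian peak: analytic dispersive pair within 2% away from edges
  x <- seq(-50, 50, length.out = 2048)
  gamma <- 2
  nim <- gamma^2 / (x^2 + gamma^2)
  expected <- gamma * x / (x^2 + gamma^2)
  got <- kramersKronig(nim)
  interior <- 250:1798
  expect_lt(max(abs(got[interior] - expected[interior])), 0.02)
  # principal-value integral oracle (direct PV sum, singular point excluded)
  xs <- seq(-30, 30, length.out = 2401)
  nims <- 4 / (xs^2 + 4)
  pv <- vapply(seq_along(xs), function(i) {
    d <- xs[i] - xs
    sum(nims[-i] / d[-i]) * (xs[2] - xs[1]) / pi
  }, 0)
  gots <- kramersKronig(nims)
  interior <- 500:1901
  expect_lt(max(abs(gots[interior] - pv[interior])), 0.02)
  expect_error(kramersKronig(rnorm(10), grid = c(1, 2, 4, 8, 16, 17, 18, 19, 20, 30)),
               "uniform")
})

test_that("van de Hulst curve matches the non-resonant closed form and stays bounded", {
  g <- fixGrid(900, 3850)
  # beta = 0 closed form to 1e-10
  rho <- seq(0.05, 12, length.out = 500)
  expect_equal(vibrospec:::.vdhQ(rho),
               2 - 4 / rho * sin(rho) + 4 / rho^2 * (1 - cos(rho)),
               tolerance = 1e-10)
  # small-particle limit
  expect_equal(extinctionCurve(c(alpha0 = 1e-12, gamma = 0.1),
                               rep(0, length(g)), g), rep(0, length(g)))
  # Q bounded over the whole default dictionary
  zref <- exp(-((g - 1650) / 100)^2) + 0.6 * exp(-((g - 1080) / 60)^2)
  for (model in c("konevskikh2", "bassan3")) {
    D <- buildDictionary(zref, extinctionParams(model), g)
    expect_true(all(is.finite(D)))
    expect_lt(max(D), 4)
    expect_true(all(apply(D, 1, stats::sd) > 0))  # non-constant rows
  }
})

test_that("dictionary cardinality follows the parameter grids", {
  g <- fixGrid()
  zref <- exp(-((g - 1400) / 80)^2)
  p1 <- extinctionParams("bassan3", a = 1.2, b = 0.5, d = 4)
  D1 <- buildDictionary(zref, p1, g)
  expect_identical(dim(D1), c(1L, length(g)))
  nim <- zref - min(zref); nim <- nim / max(nim)
  expect_identical(D1[1, ], extinctionCurve(p1$points[1, ],
                                            kramersKronig(nim, g), g,
                                            "bassan3"))
  p2 <- extinctionParams("bassan3", a = seq(1.1, 1.5, length.out = 10),
                         b = seq(0, 1, length.out = 10),
                         d = seq(2, 8, length.out = 10))
  expect_identical(nrow(buildDictionary(zref, p2, g)), 1000L)
})

test_that("dictionary compression orthogonalizes against the EMSC subspace", {
  g <- fixGrid()
  zref <- exp(-((g - 1400) / 80)^2) + 0.3 * exp(-((g - 1650) / 40)^2)
  D <- buildDictionary(zref, extinctionParams("konevskikh2"), g)
  P <- compressDictionary(D, zref, N = 7, includeLinear = TRUE, grid = g)
  # loadings orthonormal
  expect_equal(crossprod(P), diag(7), tolerance = 1e-10)
  # orthogonal to the removed subspace
  B <- cbind(1, g, zref)
  expect_lt(max(abs(crossprod(B / sqrt(colSums(B^2))[col(B)], P))), 1e-8)
  # rows equal to Zref: nothing left after orthogonalization
  Dsame <- matrix(zref, 5, length(g), byrow = TRUE)
  expect_warning(P0 <- compressDictionary(Dsame, zref, N = 3,
                                          includeLinear = TRUE, grid = g),
                 "rank")
  expect_lte(ncol(P0), 1)
  # reconstruction of dictionary rows improves monotonically with N
  err <- vapply(1:6, function(N) {
    PN <- compressDictionary(D, zref, N, includeLinear = TRUE, grid = g)
    A <- cbind(B, PN)
    sum(vapply(seq_len(nrow(D)), function(i) {
      f <- stats::lm.fit(A, D[i, ])
      sum(f$residuals^2)
    }, 0))
  }, 0)
  expect_true(all(diff(err) <= 1e-10))
})

test_that("emscFit recovers exact in-span spectra and matches a normal-equations oracle", {
  g <- fixGrid()
  zref <- exp(-((g - 1400) / 80)^2) + 0.3 * exp(-((g - 1650) / 40)^2)
  model <- emscModel(zref, g, extinctionParams("konevskikh2"), N = 6)
  # Zraw = Zref
  f0 <- emscFit(zref, model, rescaleByH = FALSE)
  expect_equal(f0$h, 1, tolerance = 1e-10)
  expect_equal(f0$c, 0, tolerance = 1e-10)
  expect_lt(max(abs(f0$eps)), 1e-10)
  expect_equal(f0$Zcorr, zref, tolerance = 1e-10)
  # Zraw = 2 Zref + 0.5 without the linear term
  m2 <- emscModel(zref, g, extinctionParams("konevskikh2"), N = 6,
                  includeLinear = FALSE)
  f2 <- emscFit(2 * zref + 0.5, m2, rescaleByH = FALSE)
  expect_equal(f2$h, 2, tolerance = 1e-8)
  expect_equal(f2$c, 0.5, tolerance = 1e-8)
  # 100 random model-generated spectra vs an independent solver
  B <- cbind(1, g, zref, model$loadings)
  set.seed(7)
  worst <- 0; worstOrth <- 0
  for (i in 1:100) {
    beta <- rnorm(ncol(B))
    z <- as.numeric(B %*% beta) + rnorm(length(g), 0, 0.01)
    f <- emscFit(z, model, rescaleByH = FALSE)
    got <- c(f$c, f$m, f$g, f$h)
    # oracle: normal equations solved independently (design order differs)
    oracle <- solve(crossprod(B), crossprod(B, z))[, 1]
    ref <- c(oracle[1], oracle[2], oracle[4:length(oracle)], oracle[3])
    worst <- max(worst, max(abs(got - ref)))
    # residual orthogonal to every design column (as cosines, so the check
    # does not depend on the column scales)
    orth <- abs(crossprod(B, f$eps)) /
      (sqrt(colSums(B^2)) * max(sqrt(sum(f$eps^2)), 1e-300))
    worstOrth <- max(worstOrth, max(orth))
  }
  expect_lt(worst, 1e-8)
  expect_lt(worstOrth, 1e-8)
})

test_that("degenerate h falls back to unrescaled with a warning", {
  g <- fixGrid()
  zref <- exp(-((g - 1400) / 80)^2)
  model <- emscModel(zref, g, extinctionParams("konevskikh2"), N = 4)
  # a spectrum orthogonal-ish to zref with no zref content
  expect_warning(f <- emscFit(rep(0, length(g)), model, rescaleByH = TRUE),
                 "unrescaled")
  expect_true(all(is.finite(f$Zcorr)))
})

test_that("corrected output is invariant to the initial reference scaling", {
  ph <- cachedPhantom(seed = 13, height = 6, width = 6, k = 2,
                      atmosphere = FALSE, mie = TRUE, baseline = "none",
                      sigma = 0.002)
  g <- wavenumbers(ph@image)
  base <- colMeans(ph@trueC %*% ph@trueS)
  opts <- crmiescOptions(nClusters = 3, maxIterations = 6, seed = 2,
                         autoStop = FALSE)
  r1 <- crmiesc(ph@image, ReferenceSpectrum(g, base), opts)
  r2 <- crmiesc(ph@image, ReferenceSpectrum(g, 2 * base), opts)
  expect_equal(specMatrix(r1$image), specMatrix(r2$image), tolerance = 1e-10)
})

test_that("an image of scaled references is corrected to the reference after one iteration", {
  g <- fixGrid()
  zref <- exp(-((g - 1400) / 80)^2) + 0.3 * exp(-((g - 1650) / 40)^2)
  scales <- c(0.5, 1, 1.7, 2.4)
  img <- HyperImage(outer(scales, zref), g, dims = c(2, 2))
  res <- crmiesc(img, ReferenceSpectrum(g, zref),
                 crmiescOptions(nClusters = 1, maxIterations = 1,
                                rescaleByH = TRUE, seed = 1))
  Z <- specMatrix(res$image)
  # corrected spectra proportional to the reference (residual of the
  # projection onto zref below 1e-6 of the norm)
  for (p in 1:4) {
    proj <- sum(Z[p, ] * zref) / sum(zref^2) * zref
    expect_lt(sqrt(sum((Z[p, ] - proj)^2)) / sqrt(sum(proj^2)), 1e-6)
  }
})

test_that("cluster refinement is monotone on a homogeneous image", {
  # one material with thickness variation: 10 vs 30 clusters differ less
  # than 1 vs 30 (more clusters refine toward the per-spectrum limit)
  g <- seq(900, 3850, by = 2)
  S <- makePureComponents(1, g, seed = 9)
  set.seed(1)
  Cmap <- matrix(runif(144, 0.5, 1.5), 144, 1)
  img0 <- HyperImage(Cmap %*% S, g, dims = c(12, 12))
  d <- addMieDistortion(img0,
                        alpha0 = exp(runif(144, log(4e-4), log(1.5e-3))),
                        gamma = exp(runif(144, log(0.15), log(0.8))),
                        amplitude = runif(144, 0.1, 0.35))
  ref <- ReferenceSpectrum(g, S[1, ])
  run <- function(k)
    specMatrix(crmiesc(d$image, ref,
                       crmiescOptions(nClusters = k, maxIterations = 6,
                                      seed = 4, autoStop = FALSE))$image)
  Z1 <- run(1); Z10 <- run(10); Z30 <- run(30)
  expect_lt(sqrt(sum((Z10 - Z30)^2)), sqrt(sum((Z1 - Z30)^2)))
})

test_that("nClusters exceeding the pixel count is reduced with a warning", {
  ph <- cachedPhantom(seed = 13, height = 2, width = 2, k = 2,
                      atmosphere = FALSE, mie = TRUE, baseline = "none",
                      sigma = 0.002)
  g <- wavenumbers(ph@image)
  ref <- ReferenceSpectrum(g, colMeans(specMatrix(ph@image)))
  expect_warning(res <- crmiesc(ph@image, ref,
                                crmiescOptions(nClusters = 30,
                                               maxIterations = 3, seed = 1,
                                               autoStop = FALSE)),
                 "reduced")
  expect_equal(nrow(specMatrix(res$image)), 4)
})
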