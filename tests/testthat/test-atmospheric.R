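# 1-D minimizer of the first-difference smoothness criterion, used as the
# independent oracle for the closed-form factor.
bruteFitFactor <- function(x, r) {
  E <- function(a) sum(diff(x - a * r)^2)
  stats::optimize(E, c(-10, 10), tol = 1e-10)$minimum
}

test_that("fitFactor equals the brute-force minimizer of the smoothness criterion", {
  g <- seq(1300, 2100, by = 2)
  atm <- interpolateToGrid(makeAtmosphereReference(), g)
  set.seed(42)
  worst <- 0
  for (i in 1:100) {
    s <- exp(-((g - runif(1, 1400, 2000)) / runif(1, 60, 200))^2) *
      runif(1, 0.5, 2)
    a0 <- runif(1, -1, 1.5)
    x <- s + a0 * atm + rnorm(length(g), 0, 0.002)
    a <- fitFactor(x, atm)
    worst <- max(worst, abs(a - bruteFitFactor(x, atm)))
  }
  expect_lt(worst, 1e-6)
  # a known 0.7 admixture over a broad band is recovered closely
  s <- exp(-((g - 1650) / 120)^2)
  a <- fitFactor(s + 0.7 * atm, atm)
  expect_lt(abs(a - 0.7), 0.05)
})

test_that("fitFactor handles the trivial and degenerate cases", {
  x <- sin(seq(0, 10, length.out = 50))
  expect_equal(fitFactor(x, x), 1)
  expect_equal(fitFactor(rep(2, 50), x), 0)
  expect_warning(a <- fitFactor(x, rep(1, 50)), "flat reference")
  expect_equal(a, 0)
})

test_that("subtractRegion only touches the region and subtracts exactly", {
  g <- fixGrid(900, 3850)
  atm <- interpolateToGrid(makeAtmosphereReference(), g)
  set.seed(1)
  X <- matrix(runif(3 * length(g)), 3)
  reg <- c(1300, 2100)
  inReg <- g >= 1300 & g <= 2100
  # zero reference in region: identity
  r0 <- atm; r0[inReg] <- 0
  expect_identical(subtractRegion(X, g, r0, reg)$x, X)
  # x = r gives x' = x - r (a = 1) inside the region
  res <- subtractRegion(atm, g, atm, reg)
  expect_equal(res$a, 1)
  expect_equal(res$x[inReg], (atm - atm)[inReg])
  expect_identical(res$x[!inReg], atm[!inReg])
  # region outside the grid: no-op with warning
  expect_warning(out <- subtractRegion(X, g, atm, c(1e4, 2e4)), "no correction")
  expect_identical(out$x, X)
})

test_that("windowed refinement reduces residuals from varying line intensities", {
  g <- seq(1300, 2100, by = 2)
  atm <- interpolateToGrid(makeAtmosphereReference(), g)
  reg <- c(1300, 2100)
  # identity cases
  set.seed(2)
  x <- runif(length(g))
  expect_equal(windowedRefinement(x, g, rep(0, length(g)), reg, 60), x)
  expect_equal(windowedRefinement(x, g, atm, reg, 60, passes = 0), x)
  # spatially varying line intensity: local factors help after global fit
  s <- exp(-((g - 1650) / 150)^2)
  aLocal <- 0.7 + 0.3 * sin((g - 1300) / 800 * 2 * pi)   # varying factor
  x <- s + aLocal * atm
  afterGlobal <- subtractRegion(x, g, atm, reg)$x
  refined <- windowedRefinement(afterGlobal, g, atm, reg, 60)
  rmsBefore <- sqrt(mean((afterGlobal - s)^2))
  rmsAfter <- sqrt(mean((refined - s)^2))
  expect_lte(rmsAfter, rmsBefore)
})

test_that("CO2 spline replacement is anchored, exact for affine data and bounded", {
  g <- fixGrid(900, 3850)
  reg <- c(2280, 2430)
  idx <- which(g >= 2280 & g <= 2430)
  # affine input reproduced to 1e-10
  x <- 0.002 * g + 1
  out <- replaceCO2Spline(x, g, reg)
  expect_equal(out[idx], x[idx], tolerance = 1e-10)
  # a large doublet is replaced within the anchor range
  x2 <- x + 3 * exp(-((g - 2350) / 15)^2)
  out2 <- replaceCO2Spline(x2, g, reg)
  anchors <- c(idx[1] - (4:1), idx[length(idx)] + (1:4))
  expect_true(all(out2[idx] >= min(x2[anchors]) - 1e-9))
  expect_true(all(out2[idx] <= max(x2[anchors]) + 1e-9))
  # region outside the span: identity
  expect_identical(replaceCO2Spline(x, g, c(1e4, 2e4)), x)
})

test_that("region smoothing preserves cubics, shrinks noise, and splices seams", {
  g <- fixGrid(900, 3850)
  regs <- list(c(1300, 2100))
  idx <- which(g >= 1300 & g <= 2100)
  # cubic polynomial untouched (SG order 3 exactness)
  x <- 1e-9 * (g - 2000)^3 + 0.001 * g
  sm <- regionSmooth(x, g, regs)
  expect_equal(sm[idx], x[idx], tolerance = 1e-9)
  # empty region list: identity
  expect_identical(regionSmooth(x, g, list()), x)
  # white noise variance strictly reduced inside the region
  set.seed(3)
  n <- rnorm(length(g))
  smn <- regionSmooth(n, g, regs)
  expect_lt(var(smn[idx]), var(n[idx]))
  expect_identical(smn[-idx], n[-idx])
})

test_that("pipeline recovers injected factors within 5% and is near-idempotent", {
  ph <- cachedPhantom(seed = 11, height = 16, width = 16, k = 3,
                      atmosphere = c(0.7, 0.3, 0.5), mie = FALSE,
                      baseline = "none", sigma = 0)
  atm <- makeAtmosphereReference()
  res <- atmosphericPipeline(ph@image, atm, atmOptions())
  f <- colMeans(res$factors)
  expect_true(all(abs(f - c(0.7, 0.3, 0.5)) / c(0.7, 0.3, 0.5) < 0.05))
  # spectra outside all regions bit-identical to input
  g <- wavenumbers(ph@image)
  outside <- g < 1300 | (g > 2100 & g < 2280) | (g > 2430 & g < 3410)
  expect_identical(specMatrix(res$image)[, outside],
                   specMatrix(ph@image)[, outside])
  # second application changes little (< 10% of the first correction)
  res2 <- atmosphericPipeline(res$image, atm, atmOptions())
  d1 <- sqrt(sum((specMatrix(res$image) - specMatrix(ph@image))^2))
  d2 <- sqrt(sum((specMatrix(res2$image) - specMatrix(res$image))^2))
  expect_lt(d2, 0.1 * d1)
})

test_that("pipeline with every step disabled is the identity", {
  ph <- cachedPhantom(seed = 11, height = 4, width = 4, k = 2,
                      atmosphere = FALSE, mie = FALSE, baseline = "none",
                      sigma = 0)
  opts <- atmOptions(waterRegions = list(), waterWindows = numeric(0),
                     co2Mode = "none", smooth = FALSE)
  res <- atmosphericPipeline(ph@image, makeAtmosphereReference(), opts)
  expect_identical(specMatrix(res$image), specMatrix(ph@image))
})

test_that("water factors from the two regions correlate on a humidity field", {
  ph <- cachedPhantom(seed = 12, height = 24, width = 24, k = 3,
                      atmosphere = TRUE, mie = FALSE, baseline = "none",
                      sigma = 0.002)
  res <- atmosphericPipeline(ph@image, makeAtmosphereReference(), atmOptions())
  expect_gt(cor(res$factors[, 1], res$factors[, 2]), 0.9)
})
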