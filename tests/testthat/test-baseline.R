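test_that("SG denoising preserves low-order polynomials and damps noise", {
  g <- fixGrid()
  poly <- 1e-9 * (g - 1300)^3 + 0.01 * g
  img <- HyperImage(rbind(poly, poly), g)
  out <- sgDenoise(img, order = 3, window = 9)
  expect_equal(specMatrix(out), specMatrix(img), tolerance = 1e-9)
  # minimal legal window (order + 2, odd)
  expect_s4_class(sgDenoise(img, order = 3, window = 5), "HyperImage")
  expect_error(sgDenoise(img, order = 3, window = 8))
  # white-noise variance reduction close to the theoretical SG gain:
  # the smoothing weights h satisfy var_out = var_in * sum(h^2)
  set.seed(5)
  n <- matrix(rnorm(20 * length(g)), 20)
  sm <- specMatrix(sgDenoise(HyperImage(n, g), 3, 9))
  h <- signal::sgolay(p = 3, n = 9)[5, ]
  gain <- sum(h^2)
  interior <- 10:(length(g) - 10)
  ratio <- var(as.numeric(sm[, interior])) / var(as.numeric(n[, interior]))
  expect_lt(abs(ratio - gain) / gain, 0.2)
})

test_that("rubberband equals a brute-force lower-hull oracle exactly", {
  # oracle: O(n^2) — for each segment between support candidates check that
  # no point lies below; build the hull by walking supports
  bruteLowerHull <- function(x, g) {
    n <- length(x)
    sup <- 1L
    i <- 1L
    while (i < n) {
      # next support: the point j minimizing the slope from i
      slopes <- (x[(i + 1):n] - x[i]) / (g[(i + 1):n] - g[i])
      j <- i + which.min(slopes)
      sup <- c(sup, j)
      i <- j
    }
    stats::approx(g[sup], x[sup], xout = g)$y
  }
  set.seed(11)
  for (i in 1:100) {
    n <- sample(10:200, 1)
    g <- sort(runif(n, 900, 1800))
    while (any(diff(g) == 0)) g <- sort(runif(n, 900, 1800))
    x <- rnorm(n) + 0.002 * g + 3 * exp(-((g - 1300) / 50)^2)
    b <- rubberband(x, g)
    expect_equal(b, bruteLowerHull(x, g), tolerance = 1e-12)
    expect_true(all(b <= x + 1e-9))
  }
  # affine spectra are their own baseline
  g <- fixGrid()
  aff <- 0.003 * g - 1
  expect_equal(rubberband(aff, g), aff, tolerance = 1e-12)
  # line + positive Gaussian: baseline is the line
  x <- aff + exp(-((g - 1300) / 40)^2)
  expect_equal(rubberband(x, g), aff, tolerance = 1e-10)
})

test_that("concave rubberband follows curved baselines from below", {
  g <- fixGrid()
  x <- 0.001 * g + exp(-((g - 1200) / 30)^2)
  expect_identical(concaveRubberband(x, g, iterations = 0), rubberband(x, g))
  # concave-curved baseline recovered with RMS < 5% of its amplitude
  base <- 0.5 + 0.3 * sin((g - 900) / 900 * pi / 1.2)
  peaks <- exp(-((g - 1200) / 20)^2) + 0.8 * exp(-((g - 1500) / 15)^2)
  b <- concaveRubberband(base + peaks, g)
  expect_lt(sqrt(mean((b - base)^2)) / diff(range(base)), 0.05)
  expect_true(all(base + peaks - b >= -1e-12))   # residual non-negative
})

test_that("AsLS flattens to the data without peaks and to a line at huge lambda", {
  g <- fixGrid()
  flat <- rep(2, length(g))
  expect_equal(asls(flat, lambda = 1e6, p = 0.01), flat, tolerance = 1e-8)
  set.seed(6)
  x <- 0.5 + 0.001 * (g - 900) + exp(-((g - 1300) / 30)^2)
  z <- asls(x, lambda = 1e13, p = 0.01)
  expect_lt(max(abs(diff(z, differences = 2))), 1e-6)   # straight line
  # known smooth baseline under positive peaks, RMS < 5% of amplitude
  base <- 0.5 + 0.3 * sin((g - 900) / 900 * pi / 1.5)
  peaks <- exp(-((g - 1200) / 20)^2) + 0.8 * exp(-((g - 1500) / 15)^2)
  zb <- asls(base + peaks, lambda = 1e5, p = 0.01)
  expect_lt(sqrt(mean((zb - base)^2)) / diff(range(base)), 0.05)
})

test_that("arPLS recovers a smooth baseline with adaptive weights", {
  g <- fixGrid()
  flat <- rep(1.5, length(g))
  expect_equal(arpls(flat, lambda = 1e6), flat, tolerance = 1e-8)
  base <- 0.5 + 0.3 * sin((g - 900) / 900 * pi / 1.5)
  peaks <- exp(-((g - 1200) / 20)^2) + 0.8 * exp(-((g - 1500) / 15)^2)
  z <- arpls(base + peaks, lambda = 1e6)
  expect_lt(sqrt(mean((z - base)^2)) / diff(range(base)), 0.05)
})

test_that("baselines are translation-equivariant", {
  g <- fixGrid()
  set.seed(8)
  x <- 0.3 * sin((g - 900) / 300) + exp(-((g - 1400) / 25)^2) +
    rnorm(length(g), 0, 0.01)
  for (fn in list(function(v) rubberband(v, g),
                  function(v) concaveRubberband(v, g),
                  function(v) asls(v),
                  function(v) arpls(v))) {
    expect_equal(fn(x + 5), fn(x) + 5, tolerance = 1e-7)
  }
})

test_that("subtractBaseline leaves near-zero baseline on a second pass", {
  # spectra with a pronounced smooth baseline under sparse positive peaks
  g <- fixGrid()
  set.seed(14)
  X <- t(replicate(4, {
    1 + 0.5 * sin((g - 900) / 900 * pi / runif(1, 1.2, 2)) +
      exp(-((g - runif(1, 1100, 1400)) / 25)^2) +
      0.7 * exp(-((g - runif(1, 1500, 1700)) / 20)^2)
  }))
  img <- HyperImage(X, g)
  for (method in c("rubberband", "asls", "arpls")) {
    opts <- baselineOptions(method)
    once <- subtractBaseline(img, opts)
    expect_identical(dim(specMatrix(once)), dim(specMatrix(img)))
    twice <- subtractBaseline(once, opts)
    d1 <- sqrt(sum((specMatrix(once) - specMatrix(img))^2))
    d2 <- sqrt(sum((specMatrix(twice) - specMatrix(once))^2))
    expect_lt(d2, 0.15 * d1)
  }
  expect_identical(subtractBaseline(img, baselineOptions("none")), img)
})
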