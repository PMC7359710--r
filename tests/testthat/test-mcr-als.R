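test_that("svdGuide returns descending singular values with the right energy", {
  set.seed(3)
  # rank-2 noiseless
  D <- outer(runif(30), runif(40)) + outer(runif(30), runif(40))
  s <- svdGuide(D)
  expect_true(all(diff(s) <= 1e-12))
  expect_lt(s[3], 1e-10 * s[1])
  expect_equal(sum(s^2), sum(D^2), tolerance = 1e-8)
  # phantom with k components + mild noise: gap after sigma_k
  ph <- cachedPhantom(seed = 15, height = 16, width = 16, k = 4,
                      atmosphere = FALSE, mie = FALSE, baseline = "none",
                      sigma = 0.002)
  sp <- svdGuide(specMatrix(ph@image))
  expect_gt(sp[4] / sp[5], 5)
})

test_that("SIMPLISMA selects the pure variables of a block matrix", {
  # 6 x 8 toy matrix with 3 mutually exclusive pure variables (columns
  # 2, 5, 7); other columns are mixtures
  c1 <- c(1, 2, 3, 0, 0, 0)
  c2 <- c(0, 0, 0, 2, 1, 0)
  c3 <- c(0, 0, 1, 0, 2, 3)
  D <- cbind(c1 + c2, c1, c1 + c3, c2 + c3, c2, c1 + c2 + c3, c3,
             0.5 * c1 + 0.5 * c2)
  sel <- simplisma(D, 3, alpha = 1, axis = "columns")
  expect_setequal(sel$indices, c(2, 5, 7))
  # k = 1 equals the direct purity scan
  mu <- colMeans(D)
  sg <- sqrt(colMeans(D^2) - mu^2)
  f <- 1 / 100 * max(mu)
  expect_identical(simplisma(D, 1, alpha = 1)$indices,
                   which.max((sg / (mu + f)) *
                               diag(crossprod(sweep(D, 2,
                                 sqrt(mu^2 + (sg + f)^2), "/")) / nrow(D))))
  # permuting rows permutes row-mode selection identically: the selected
  # positions in the permuted matrix point at the same original rows
  # (a small deterministic perturbation breaks purity ties first)
  Dr <- D * (1 + 0.01 * outer(seq_len(6), seq_len(8)))
  perm <- c(3, 1, 4, 2, 6, 5)
  selRows <- simplisma(Dr, 2, axis = "rows")$indices
  selPerm <- simplisma(Dr[perm, ], 2, axis = "rows")$indices
  expect_identical(sort(as.integer(perm[selPerm])), sort(selRows))
  expect_error(simplisma(D, 7), "between 1 and")
  expect_warning(simplisma(D - 0.1, 2), "non-negative")
})

test_that("fcnnls agrees with a per-column NNLS oracle", {
  set.seed(21)
  worst <- 0
  for (i in 1:30) {
    m <- sample(10:60, 1); k <- sample(2:6, 1); n <- sample(1:10, 1)
    A <- matrix(rnorm(m * k), m)
    B <- matrix(rnorm(m * n), m)
    X <- vibrospec:::.fcnnls(A, B)
    expect_true(all(X >= 0))
    for (j in seq_len(n)) {
      ref <- pracma::lsqnonneg(A, B[, j])$x
      worst <- max(worst, max(abs(X[, j] - ref)))
    }
  }
  expect_lt(worst, 1e-8)
})

test_that("MCR-ALS recovers a noiseless factorization with pure pixels", {
  ph <- cachedPhantom(seed = 16, height = 16, width = 16, k = 4,
                      atmosphere = FALSE, mie = FALSE, baseline = "none",
                      sigma = 0)
  D <- specMatrix(ph@image)
  res <- mcrAls(D, mcrConfig(4, relTol = 1e-8))
  expect_lt(utils::tail(residualHistory(res), 1), 1e-4)  # < 1e-6 relative
  expect_gt(minMatchedCosine(ph@trueS, pureSpectra(res)), 0.999)
  expect_true(all(concentrations(res) >= 0))
  expect_true(all(pureSpectra(res) >= 0))
  # residual history non-increasing until the stop iteration
  h <- residualHistory(res)
  if (res@stopReason == "error_increase") h <- h[-length(h)]
  expect_true(all(diff(h) <= 1e-10))
})

test_that("rank-1 data is recovered within two iterations", {
  set.seed(2)
  cvec <- runif(25, 0.1, 1); svec <- runif(50, 0.1, 1)
  D <- outer(cvec, svec)
  res <- mcrAls(D, mcrConfig(1, relTol = 1e-6))
  expect_lte(length(residualHistory(res)), 2)
  expect_lt(residualHistory(res)[1], 1e-8)
})

test_that("each ALS half-step never increases the residual", {
  ph <- cachedPhantom(seed = 16, height = 8, width = 8, k = 3,
                      atmosphere = FALSE, mie = FALSE, baseline = "none",
                      sigma = 0.005)
  D <- pmax(specMatrix(ph@image), 0)
  S <- t(simplisma(D, 3, axis = "rows")$profiles)
  err <- Inf
  for (it in 1:5) {
    C <- t(vibrospec:::.fcnnls(t(S), t(D)))
    e1 <- sqrt(sum((D - C %*% S)^2))
    expect_lte(e1, err + 1e-10)
    S <- vibrospec:::.fcnnls(C, D)
    e2 <- sqrt(sum((D - C %*% S)^2))
    expect_lte(e2, e1 + 1e-10)
    err <- e2
  }
})

test_that("ROI polygons select pixels by the even-odd rule", {
  ph <- cachedPhantom(seed = 16, height = 4, width = 4, k = 2,
                      atmosphere = FALSE, mie = FALSE, baseline = "none",
                      sigma = 0)
  # polygon covering the whole image: all pixels
  all4 <- applyRoi(ph@image, cbind(c(0, 5, 5, 0), c(0, 0, 5, 5)))
  expect_length(all4$indices, 16)
  # right triangle vs per-pixel brute-force even-odd test
  tri <- cbind(c(0.5, 4.5, 0.5), c(0.5, 0.5, 4.5))
  mask <- roiMask(tri, c(4, 4))
  pointInPoly <- function(px, py, vx, vy) {
    inside <- FALSE
    j <- length(vx)
    for (i in seq_along(vx)) {
      if ((vy[i] > py) != (vy[j] > py) &&
          px < (vx[j] - vx[i]) * (py - vy[i]) / (vy[j] - vy[i]) + vx[i])
        inside <- !inside
      j <- i
    }
    inside
  }
  expected <- logical(16)
  for (rw in 1:4) for (cl in 1:4)
    expected[(rw - 1) * 4 + cl] <- pointInPoly(cl, rw, tri[, 1], tri[, 2])
  expect_identical(mask, expected)
  expect_error(roiMask(cbind(c(1, 2, 3), c(1, 2, 3)), c(4, 4)), "degenerate")
  # ROI invariance: decomposition of the submatrix equals a standalone run
  ph8 <- cachedPhantom(seed = 16, height = 8, width = 8, k = 2,
                       atmosphere = FALSE, mie = FALSE, baseline = "none",
                       sigma = 0.002)
  half <- roiMask(cbind(c(0.5, 8.5, 8.5, 0.5), c(0.5, 0.5, 5.5, 5.5)),
                  c(8, 8))
  D <- pmax(specMatrix(ph8@image), 0)
  res1 <- mcrAls(D, mcrConfig(2), roi = half)
  res2 <- mcrAls(D[half, , drop = FALSE], mcrConfig(2))
  expect_identical(concentrations(res1), concentrations(res2))
  expect_identical(pureSpectra(res1), pureSpectra(res2))
})
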