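test_that("the spectral-histogram matrix has the right shape and stationarity", {
  const <- matrix(0.5, 40, 40)
  Y <- makeFeatureMatrix(const)
  expect_equal(dim(Y$values), c(77L, 1600L))
  expect_lt(max(apply(Y$values, 1L, function(r) diff(range(r)))), 1e-6)
  expect_error(makeFeatureMatrix(matrix(0, 5, 5), windowSize = 9), "smaller")
})

test_that("two textures are far apart in feature space relative to within-texture spread", {
  f <- textureDiskPhantom(2, size = 192, radius = 48)
  Y <- makeFeatureMatrix(f$image)$values
  rr <- matrix(1:192, 192, 192); cc <- t(rr)
  rad <- sqrt((rr - 96.5)^2 + (cc - 96.5)^2)
  inn <- which(rad < 30); out <- which(rad > 68 & rad < 90)
  mI <- rowMeans(Y[, inn]); mO <- rowMeans(Y[, out])
  between <- sqrt(sum((mI - mO)^2))
  spread <- function(idx, m) mean(sqrt(colSums((Y[, idx] - m)^2)))
  within <- (spread(inn, mI) + spread(out, mO)) / 2
  expect_gt(between, 3 * within)
})

test_that("the initial level set is a signed distance to the seed circle", {
  st <- initLevelSet(c(128, 128), c(64, 64))
  expect_equal(st$phi[64, 64], -32)          # radius = width/4 exactly
  g <- odedema:::gradCentral(st$phi)
  mag <- sqrt(g$dr^2 + g$dc^2)
  rr <- matrix(1:128, 128, 128); cc <- t(rr)
  offCenter <- sqrt((rr - 64)^2 + (cc - 64)^2) > 2
  expect_lt(max(abs(mag[offCenter] - 1)), 0.05)
  ctr <- extractContour(st$phi)
  radii <- sqrt((ctr[, 1] - 64)^2 + (ctr[, 2] - 64)^2)
  expect_lt(max(abs(radii - 32)), 1)
  expect_error(initLevelSet(c(64, 64), c(200, 10)), "outside")
})

test_that("region weights solve the factorization least squares", {
  expect_equal(odedema:::heavisideEpsFn(0, 1.5), 0.5)
  # exact recovery with orthogonal representatives
  set.seed(3)
  q <- qr.Q(qr(matrix(rnorm(77 * 2), 77, 2)))
  beta0 <- matrix(runif(2 * 50), 2, 50)
  w <- computeRegionWeights(q %*% beta0, q)
  expect_lt(max(abs(w$beta - beta0)), 1e-10)
  # identical columns are a numerical error
  r1 <- matrix(rnorm(77), 77, 1)
  expect_error(computeRegionWeights(q %*% beta0, cbind(r1, r1)),
               "collinear")
  # agreement with an SVD pseudo-inverse oracle on random problems
  for (i in 1:20) {
    set.seed(100 + i)
    R <- matrix(rnorm(12 * 2), 12, 2)
    Y <- matrix(rnorm(12 * 30), 12, 30)
    expect_lt(max(abs(computeRegionWeights(Y, R)$beta -
                      lsqPinvOracle(Y, R))), 1e-8)
  }
})

test_that("representatives are the per-region mean features at a clean split", {
  f <- textureDiskPhantom(3)
  st <- initLevelSet(c(128, 128), f$center, radius = 32)   # true boundary
  Y <- makeFeatureMatrix(f$image)
  R <- updateRepresentatives(Y, st$phi)
  hard <- cbind(rowMeans(Y$values[, as.numeric(st$phi) < 0]),
                rowMeans(Y$values[, as.numeric(st$phi) >= 0]))
  expect_lt(max(abs(R - hard)) / max(abs(hard)), 0.02)
  # phi > 0 everywhere leaves no object region
  expect_error(updateRepresentatives(Y, st$phi + 1000), "degenerate")
})

test_that("evolution is stationary when forces balance and flags divergence", {
  phi <- matrix(rep(seq_len(40) - 20.5, each = 40), 40, 40)  # |grad| = 1
  Yv <- matrix(1, 4, 1600)
  R <- cbind(c(1, 0, 0, 0), c(0, 1, 0, 0))
  wts <- list(omegaO = rep(0.5, 1600), omegaB = rep(0.5, 1600),
              beta = rbind(rep(0.5, 1600), rep(0.5, 1600)))
  st <- list(phi = phi, iteration = 0L)
  out <- evolveStep(st, Yv, R, fgvfParams(), weights = wts)
  expect_lt(max(abs(out$phi - phi)), 1e-10)
  # a non-finite update is a divergence error
  wts2 <- list(omegaO = rep(1e308, 1600), omegaB = rep(-1e308, 1600))
  expect_error(evolveStep(st, Yv, R, fgvfParams(dt = 1e6), weights = wts2),
               "divergence")
})

test_that("the convergence rule applies the 0.05 px displacement threshold", {
  C <- circleContour(c(50, 50), 20)
  expect_true(checkConvergence(C, C))
  shift04 <- sweep(C, 2L, c(0.04, 0.04), "+")
  expect_true(checkConvergence(shift04, C))
  shift06 <- sweep(C, 2L, c(0.06, 0.0), "+")
  expect_false(checkConvergence(shift06, C))
  expect_error(checkConvergence(NULL, C), "empty")
})

test_that("a full segmentation run recovers the disk with sound diagnostics", {
  run <- fixSegRun()
  res <- run$res
  expect_gte(diceOf(res$mask, run$fix$mask), 0.90)
  expect_true(res$diagnostics$converged)
  expect_equal(energyViolations(res$diagnostics$energyTrace), 0L)
  expect_lte(bandDeviation(res$diagnostics$phi), 0.2)
  # contract for a bounded run: valid mask, non-converged flag
  short <- segmentOD(run$fix$image, run$fix$center,
                     fgvfParams(maxIters = 1))
  expect_false(short$diagnostics$converged)
  expect_equal(short$diagnostics$iterations, 1L)
  expect_equal(dim(short$mask), c(128L, 128L))
})

test_that("segmentation is invariant to affine intensity rescaling", {
  f <- textureDiskPhantom(6)
  res1 <- segmentOD(f$image, f$center)
  res2 <- segmentOD(0.5 * f$image + 0.2, f$center)
  d1 <- diceOf(res1$mask, f$mask)
  d2 <- diceOf(res2$mask, f$mask)
  expect_lt(abs(d1 - d2), 0.02)
})
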