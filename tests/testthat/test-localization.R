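test_that("parabola fit is exact on noiseless data and robust to noise", {
  rows <- seq(100, 300, by = 2)
  cols <- 0.01 * (rows - 200)^2 + 100
  fit <- fitParabola(cbind(rows, cols))
  expect_equal(unname(fit$vertex), c(200, 100), tolerance = 1e-6)
  # Gaussian noise sigma = 2 on col: vertex within 5 px
  set.seed(0)
  fitN <- fitParabola(cbind(rows, cols + rnorm(length(rows), 0, 2)))
  expect_lt(sqrt(sum((fitN$vertex - c(200, 100))^2)), 5)
  expect_error(fitParabola(cbind(c(1, 2), c(3, 4))), "3 points")
  expect_error(fitParabola(cbind(1:10, 2 * (1:10) + 1)), "degenerate")
})

test_that("line convergence is exact for concurrent lines, errors when parallel", {
  mkseg <- function(theta, center = c(150, 150)) {
    t <- seq(-30, 30, by = 1)
    cbind(center[1] + t * sin(theta), center[2] + t * cos(theta))
  }
  pt <- fitLineConvergence(list(mkseg(0.3), mkseg(1.2), mkseg(2.1)))
  expect_equal(unname(pt), c(150, 150), tolerance = 1e-6)
  horiz1 <- cbind(rep(50, 20), seq_len(20))
  horiz2 <- cbind(rep(80, 20), seq_len(20))
  expect_error(fitLineConvergence(list(horiz1, horiz2)), "parallel")
  expect_error(fitLineConvergence(list(mkseg(0.3))), "2 usable")
})

test_that("vessel segmentation recovers the phantom tree", {
  ph <- fixPhantom()
  vm <- fixVesselMap()
  expect_equal(dim(vesselMask(vm)), dim(vesselMask(ph)))
  expect_gte(diceOracle(vesselMask(vm), vesselMask(ph)), 0.7)
  # skeleton is a subset of the mask, segments lie on the skeleton
  expect_true(all(vm@skeleton <= vm@mask))
  seg <- vm@segments[[which.max(vapply(vm@segments, nrow, numeric(1)))]]
  expect_true(all(vm@skeleton[seg] == 1))
})

test_that("a constant image yields an empty vessel map", {
  img <- fundusImage(array(0.5, c(200, 200, 3)))
  vm <- segmentVessels(img, retinaGeometry(c(100, 100), 190))
  expect_equal(sum(vesselMask(vm)), 0L)
  expect_length(vm@segments, 0L)
})

test_that("network assessment separates complete from fragmented trees", {
  ph <- fixPhantom()
  a1 <- assessNetwork(fixVesselMap(), ph@geometry)
  expect_equal(a1$status, "complete")
  phe <- generatePhantom(phantomSpec(classLabel = "edematous",
                                     odRadiusFrac = 0.12,
                                     vesselCompleteness = 0.3, rngSeed = 4))
  a2 <- assessNetwork(segmentVessels(phe@image, phe@geometry), phe@geometry)
  expect_equal(a2$status, "incomplete")
  empty <- new("VesselMap", mask = matrix(0L, 10, 10),
               skeleton = matrix(0L, 10, 10), segments = list())
  expect_error(assessNetwork(empty, ph@geometry), "empty")
})

test_that("hybrid localization lands inside the true disk for both classes", {
  ph <- fixPhantom()
  loc <- localizeOD(ph@image, ph@geometry, vm = fixVesselMap())
  expect_equal(loc@method, "parabola")
  expect_false(loc@warning)
  expect_true(scoreLocalization(loc, odMask(ph)))
  phe <- fixEdemaPhantom()
  loce <- localizeOD(phe@image, phe@geometry)
  expect_equal(loce@method, "convergence")
  expect_true(scoreLocalization(loce, odMask(phe)))
})

test_that("a vessel-free image falls back to the brightest region, flagged", {
  rr <- matrix(seq_len(300), 300, 300); cc <- t(rr)
  retina <- ((rr - 150)^2 + (cc - 150)^2) <= 140^2
  disk <- ((rr - 150)^2 + (cc - 110)^2) <= 24^2
  px <- array(0, c(300, 300, 3))
  for (ch in 1:3) px[, , ch] <- 0.35 * retina + 0.5 * disk
  loc <- localizeOD(fundusImage(px), retinaGeometry(c(150, 150), 280))
  expect_true(loc@warning)
  expect_equal(loc@method, "brightest_fallback")
  expect_lt(sqrt(sum((odCenter(loc) - c(150, 110))^2)), 24)
})
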