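test_that("the ROI is a D/3 square at the right offset, clipped when needed", {
  px <- array(0.4, c(600, 600, 3))
  img <- fundusImage(px)
  geom <- retinaGeometry(c(300, 300), 300)
  roi <- extractROI(img, c(150, 150), geom)
  expect_equal(dim(roi@pixels)[1:2], c(100L, 100L))
  expect_equal(roi@offset, c(100, 100))
  expect_equal(roi@widthPx, 100)
  expect_false(roi@clipped)
  clipped <- extractROI(img, c(10, 300), geom)
  expect_true(clipped@clipped)
  expect_lt(dim(clipped@pixels)[1], 100L)
  expect_error(extractROI(img, c(-5, 10), geom), "outside")
})

test_that("ROI extraction is translation equivariant in the location", {
  img <- fundusImage(array(runif(600 * 600 * 3), c(600, 600, 3)))
  geom <- retinaGeometry(c(300, 300), 300)
  r1 <- extractROI(img, c(200, 200), geom)
  r2 <- extractROI(img, c(217, 233), geom)
  expect_equal(r2@offset - r1@offset, c(17, 33))
  expect_equal(dim(r1@pixels), dim(r2@pixels))
})

test_that("CLAHE passes a flat field through and stretches low contrast", {
  flat <- new("ROIPatch", pixels = array(0.5, c(64, 64, 3)),
              offset = c(1, 1), widthPx = 64, clipped = FALSE)
  fe <- enhanceContrast(flat)
  expect_lt(max(abs(fe@pixels - 0.5)), 1 / 255)
  expect_equal(dim(fe@pixels), dim(flat@pixels))
  set.seed(1)
  m <- matrix(0.45, 96, 96); m[, 49:96] <- 0.55
  m <- pmin(pmax(m + matrix(rnorm(96 * 96, 0, 0.01), 96), 0), 1)
  low <- new("ROIPatch", pixels = array(rep(m, 3), c(96, 96, 3)),
             offset = c(1, 1), widthPx = 96, clipped = FALSE)
  le <- enhanceContrast(low)
  sdL <- function(p) sd(odedema:::rgb2lab(p)[, , 1])
  expect_gt(sdL(le@pixels), sdL(low@pixels))
})

test_that("harmonic fill reproduces ramps and obeys the maximum principle", {
  ramp <- matrix(seq(0, 1, length.out = 60), 60, 60)
  arr <- array(0, c(60, 60, 3)); arr[, , 2] <- ramp
  roi <- new("ROIPatch", pixels = arr, offset = c(1, 1), widthPx = 60,
             clipped = FALSE)
  mask <- matrix(0L, 60, 60); mask[20:35, 18:40] <- 1L
  out <- removeVessels(roi, mask, sigma = 0)
  expect_lt(max(abs(out - ramp)), 1e-3)      # ramps are harmonic

  # phantom ROI: 4-neighbor mean property and maximum principle per region
  b <- fixRoiBundle()
  vf <- removeVessels(b$roi, b$vroi)
  filled <- t(EBImage::imageData(EBImage::dilate(
    EBImage::Image(t(b$vroi * 1)), EBImage::makeBrush(3, "box")))) > 0
  idx <- which(filled, arr.ind = TRUE)
  interior <- idx[idx[, 1] > 1 & idx[, 1] < nrow(vf) &
                  idx[, 2] > 1 & idx[, 2] < ncol(vf), , drop = FALSE]
  sh <- function(dr, dc) vf[cbind(interior[, 1] + dr, interior[, 2] + dc)]
  nbMean <- (sh(-1, 0) + sh(1, 0) + sh(0, -1) + sh(0, 1)) / 4
  expect_lt(max(abs(vf[cbind(interior[, 1], interior[, 2])] - nbMean)), 1e-3)
  lab <- odedema:::label8(filled)
  for (k in seq_len(max(lab))) {
    reg <- lab == k
    grow <- odedema:::shiftMat(reg, 1L, 0L) | odedema:::shiftMat(reg, -1L, 0L) |
            odedema:::shiftMat(reg, 0L, 1L) | odedema:::shiftMat(reg, 0L, -1L)
    boundary <- grow & !filled
    if (!any(boundary)) next
    expect_gte(min(vf[reg]) + 1e-12, min(vf[boundary]))
    expect_lte(max(vf[reg]) - 1e-12, max(vf[boundary]))
  }
})

test_that("vessel removal degenerate cases behave", {
  b <- fixRoiBundle()
  empty <- matrix(0L, b$hw[1], b$hw[2])
  out <- removeVessels(b$roi, empty, sigma = 1.5)
  expect_equal(out, odedema:::gaussBlur(b$roi@pixels[, , 2], 1.5))
  full <- matrix(1L, b$hw[1], b$hw[2])
  expect_error(removeVessels(b$roi, full), "entire patch")
  expect_error(removeVessels(b$roi, matrix(0L, 10, 10)), "shape")
})
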