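test_that("GLCM of degenerate and stripe images matches hand counts", {
  const <- matrix(0.4, 16, 16)
  p <- computeGLCM(const, levels = 8)[[1]]
  expect_equal(sum(p == 1), 1L)
  expect_equal(sum(p), 1)
  # features on the delta matrix
  f <- tryCatch(glcmFeatures(p), error = function(e) e)
  expect_s3_class(f, "error")                  # corrp undefined
  expect_match(conditionMessage(f), "correlation")
  # two-level vertical stripes, horizontal offset: only cross pairs
  stripes <- matrix(rep(c(0.2, 0.8), 8), 16, 16, byrow = TRUE)
  ps <- computeGLCM(stripes, levels = 2, offsets = list(c(0L, 1L)))[[1]]
  expect_equal(ps[1, 2], 0.5)
  expect_equal(ps[2, 1], 0.5)
  fs <- glcmFeatures(ps)
  expect_equal(unname(fs["contr"]), 1)
  expect_equal(unname(fs["dissi"]), 1)
  expect_equal(unname(fs["homop"]), 0.5)
  expect_equal(unname(fs["energy"]), 0.5)
  expect_equal(unname(fs["maxpr"]), 0.5)
  expect_equal(unname(fs["entro"]), log(2))
})

test_that("GLCM and its features match the brute-force oracle", {
  offsets <- list(c(0L, 1L), c(-1L, 1L), c(-1L, 0L), c(-1L, -1L))
  set.seed(42)
  for (i in 1:20) {
    img <- matrix(runif(144), 12, 12)
    for (ng in c(2L, 4L, 8L, 16L)) {
      mats <- computeGLCM(img, levels = ng, offsets = offsets)
      for (k in seq_along(offsets)) {
        pOr <- glcmOracle(img, ng, offsets[[k]])
        expect_lt(max(abs(mats[[k]] - pOr)), 1e-12)
        expect_lt(max(abs(glcmFeatures(mats[[k]]) -
                          glcmFeaturesOracle(pOr))), 1e-10)
      }
    }
  }
})

test_that("vessel features count components and moments correctly", {
  m <- matrix(0L, 40, 40)
  m[2:9, 2:6] <- 1L      # 40 px
  m[20:25, 10:14] <- 1L  # 30 px
  m[32:36, 30:31] <- 1L  # 10 px
  od <- matrix(0L, 40, 40); od[1:27, 1:20] <- 1L   # covers two blobs
  half <- matrix(rep(c(0.2, 0.8), each = 800), 40, 40)
  v <- vesselFeatures(m, od, half)
  expect_equal(unname(v["vdi"]), 3)
  expect_equal(unname(v["vdip"]), 2)
  expect_equal(unname(v["largest_vessel_area"]), 40)
  expect_equal(unname(v["mean_vessel_area"]), 80 / 3)
  expect_equal(unname(v["sigma"]), 0.3)
  expect_equal(unname(v["kurtosis"]), 1)
  expect_error(vesselFeatures(m, od, matrix(0.5, 40, 40)), "kurtosis")
})

test_that("kurtosis of clipped normal intensities is 3 within 0.1", {
  set.seed(0)
  x <- matrix(pmin(pmax(rnorm(1e5, 0.5, 0.1), 0), 1), 250, 400)
  v <- vesselFeatures(matrix(0L, 250, 400), matrix(0L, 250, 400), x)
  expect_lt(abs(unname(v["kurtosis"]) - 3), 0.1)
})

test_that("color features satisfy their closed forms", {
  mk <- function(arr) new("ROIPatch", pixels = arr, offset = c(1, 1),
                          widthPx = dim(arr)[1], clipped = FALSE)
  gray <- mk(array(0.5, c(64, 64, 3)))
  cg <- colorFeatures(gray)
  expect_equal(unname(cg["sharpness"]), 0)
  expect_equal(unname(cg["saturation"]), 0)
  red <- array(0, c(64, 64, 3)); red[, , 1] <- 1
  cr <- colorFeatures(mk(red))
  expect_equal(unname(cr["hue"]), 0)
  expect_equal(unname(cr["saturation"]), 1)
  expect_equal(unname(cr["brightness"]), 1)
  # constant-slope ramp: mean gradient norm equals the slope up to the
  # border columns (one-sided mirror differences vanish there)
  w <- 128
  ramp <- array(rep(matrix(seq_len(w) / w, w, w, byrow = TRUE), 3),
                c(w, w, 3))
  cramp <- colorFeatures(mk(ramp))
  expect_lt(abs(unname(cramp["sharpness"]) * w - 1), 0.02)
})

test_that("line profile samples round(D/2) pixels with exact statistics", {
  alt <- matrix(rep(c(0, 1), 300), 600, 600, byrow = TRUE)
  px <- array(rep(alt, 3), c(600, 600, 3))
  img <- fundusImage(px)
  geom <- retinaGeometry(c(300, 300), 400)
  v <- lineProfileFeatures(img, c(300, 300), geom)
  expect_equal(unname(v["profile_mean"]), 0.5)
  expect_equal(unname(v["profile_min"]), 0)
  expect_equal(unname(v["profile_max"]), 1)
  expect_equal(unname(v["profile_std"]), 0.5)
  expect_false(attr(v, "clipped"))
  const <- fundusImage(array(0.3, c(600, 600, 3)))
  vc <- lineProfileFeatures(const, c(300, 300), geom)
  expect_equal(as.vector(vc), c(0.3, 0.3, 0.3, 0), tolerance = 1e-12)
  # clipping flag near the border
  vclip <- lineProfileFeatures(img, c(300, 30), geom)
  expect_true(attr(vclip, "clipped"))
})

test_that("the assembled 27-vector is named, ordered, finite and deterministic", {
  b <- fixRoiBundle()
  fv <- extractAllFeatures(b$ph@image, b$ph@geometry, b$loc, b$gt,
                           fixVesselMap())
  expect_length(fv, 27L)
  expect_identical(names(fv), featureNames27())
  expect_true(all(is.finite(fv)))
  fv2 <- extractAllFeatures(b$ph@image, b$ph@geometry, b$loc, b$gt,
                            fixVesselMap())
  expect_identical(fv, fv2)
})

test_that("a constant image propagates a named feature error", {
  px <- array(0.5, c(400, 400, 3))
  img <- fundusImage(px)
  geom <- retinaGeometry(c(200, 200), 384)
  loc <- new("ODLocation", center = c(200, 200), method = "convergence")
  vm <- new("VesselMap", mask = matrix(0L, 400, 400),
            skeleton = matrix(0L, 400, 400), segments = list())
  side <- round(384 / 3)
  expect_error(
    extractAllFeatures(img, geom, loc, matrix(1L, side, side), vm),
    "kurtosis|correlation")
})
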