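test_that("phantom generation is deterministic and honors the D/6 disk size", {
  sp <- phantomSpec(rngSeed = 11)
  p1 <- generatePhantom(sp)
  p2 <- generatePhantom(sp)
  expect_identical(imagePixels(p1), imagePixels(p2))
  expect_identical(odMask(p1), odMask(p2))
  # D = 480: the non-edematous disk mask has diameter 80 +/- 1
  ph <- generatePhantom(phantomSpec(size = c(500L, 500L), rngSeed = 2))
  D <- 0.96 * 500
  estDiam <- 2 * sqrt(sum(odMask(ph)) / pi)
  expect_lt(abs(estDiam - D / 6), 1)
})

test_that("an OD outside the retina is a spec error", {
  expect_error(phantomSpec(odCenter = c(200, 30)), "inside the retina")
})

test_that("vessel tree is connected when complete, fragmented otherwise", {
  ph <- generatePhantom(phantomSpec(rngSeed = 5))
  skel <- odedema:::thinZS(vesselMask(ph))
  expect_equal(length(odedema:::componentSizes8(skel)), 1L)
  phf <- generatePhantom(phantomSpec(classLabel = "edematous",
                                     odRadiusFrac = 0.12,
                                     vesselCompleteness = 0.4, rngSeed = 5))
  skf <- odedema:::thinZS(vesselMask(phf))
  expect_gt(length(odedema:::componentSizes8(skf)), 1L)
})

test_that("the disk is brighter than the surrounding retina", {
  for (seed in c(1, 4, 9)) {
    ph <- generatePhantom(phantomSpec(rngSeed = seed))
    g <- odedema:::toGray(imagePixels(ph))
    rr <- matrix(seq_len(400), 400, 400); cc <- t(rr)
    D <- retinaDiameter(ph@geometry)
    ctr <- retinaCenter(ph@geometry)
    retina <- ((rr - ctr[1])^2 + (cc - ctr[2])^2) <= (D / 2)^2
    expect_gt(mean(g[odMask(ph) == 1]),
              mean(g[retina & odMask(ph) == 0]))
  }
})

test_that("edematous boundaries have weaker gradients than matched sharp ones", {
  for (seed in c(2, 6)) {
    base <- list(size = c(400L, 400L), odRadiusFrac = 1 / 12, rngSeed = seed)
    phN <- generatePhantom(do.call(phantomSpec, base))
    phE <- generatePhantom(do.call(phantomSpec,
      c(base, list(classLabel = "edematous", edgeBlurSigma = 4))))
    bandGrad <- function(ph) {
      g <- odedema:::gradCentral(odedema:::toGray(imagePixels(ph)))
      mag <- sqrt(g$dr^2 + g$dc^2)
      m <- odMask(ph)
      dil <- odedema:::shiftMat(m, 1L, 0L) | odedema:::shiftMat(m, -1L, 0L) |
             odedema:::shiftMat(m, 0L, 1L) | odedema:::shiftMat(m, 0L, -1L)
      mean(mag[dil & !m])          # one-pixel outer boundary band
    }
    expect_lt(bandGrad(phE), bandGrad(phN))
  }
})

test_that("cohorts are balanced, seeded and reproducible", {
  c1 <- generateCohort(4, 3, seed = 21)
  expect_length(c1$phantoms, 7L)
  expect_equal(sum(c1$manifest$label == "edematous"), 4L)
  expect_equal(sum(c1$manifest$label == "non_edematous"), 3L)
  c2 <- generateCohort(4, 3, seed = 21)
  expect_identical(imagePixels(c1$phantoms[[5]]),
                   imagePixels(c2$phantoms[[5]]))
  c3 <- generateCohort(0, 2, seed = 1)
  expect_length(c3$phantoms, 2L)
  expect_true(all(c3$manifest$label == "non_edematous"))
})

test_that("texture disk fixtures are seeded and carry their mask", {
  f1 <- textureDiskPhantom(5)
  f2 <- textureDiskPhantom(5)
  expect_identical(f1$image, f2$image)
  expect_equal(dim(f1$image), c(128L, 128L))
  expect_equal(sum(f1$mask), sum(((row(f1$mask) - 64.5)^2 +
                                  (col(f1$mask) - 64.5)^2) <= 32^2))
})
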