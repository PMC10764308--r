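# Shared fixtures (built once per test run) and independent oracles.

fixEnv <- new.env()

# memoized standard phantoms and their pipeline products
fixPhantom <- function() {
  if (is.null(fixEnv$ph)) fixEnv$ph <- generatePhantom(phantomSpec(rngSeed = 3))
  fixEnv$ph
}

fixEdemaPhantom <- function() {
  if (is.null(fixEnv$phe))
    fixEnv$phe <- generatePhantom(phantomSpec(
      classLabel = "edematous", odRadiusFrac = 0.12, edgeBlurSigma = 4,
      vesselCompleteness = 0.35, rngSeed = 9))
  fixEnv$phe
}

fixVesselMap <- function() {
  if (is.null(fixEnv$vm)) {
    ph <- fixPhantom()
    fixEnv$vm <- segmentVessels(ph@image, ph@geometry)
  }
  fixEnv$vm
}

# ROI-frame products of the standard phantom
fixRoiBundle <- function() {
  if (is.null(fixEnv$roiB)) {
    ph <- fixPhantom()
    loc <- localizeOD(ph@image, ph@geometry, vm = fixVesselMap())
    roi <- extractROI(ph@image, loc, ph@geometry)
    hw <- dim(roi@pixels)[1:2]; off <- roi@offset
    crop <- function(m) m[off[1]:(off[1] + hw[1] - 1),
                          off[2]:(off[2] + hw[2] - 1)]
    fixEnv$roiB <- list(ph = ph, loc = loc, roi = roi, off = off, hw = hw,
                        vroi = crop(vesselMask(fixVesselMap())),
                        gt = crop(odMask(ph)))
  }
  fixEnv$roiB
}

# one completed texture-fixture segmentation, shared by several tests
fixSegRun <- function() {
  if (is.null(fixEnv$segRun)) {
    f <- textureDiskPhantom(1)
    fixEnv$segRun <- list(fix = f,
                          res = segmentOD(f$image, f$center))
  }
  fixEnv$segRun
}

# small end-to-end experiment shared by the pipeline tests
fixSmallExperiment <- function() {
  if (is.null(fixEnv$smallExp)) {
    coh <- generateCohort(2, 2, seed = 31, size = c(320L, 320L))
    fixEnv$smallExp <- list(coh = coh,
                            rep = runExperiment(coh, seed = 31, k = 2))
  }
  fixEnv$smallExp
}

# ---- independent oracles ----------------------------------------------------

# brute-force GLCM by explicit pixel-pair double loop
glcmOracle <- function(img, levels, off, symmetric = TRUE) {
  lvl <- pmin(floor(img * levels), levels - 1L) + 1L
  p <- matrix(0, levels, levels)
  nr <- nrow(img); nc <- ncol(img)
  for (r in seq_len(nr)) for (c in seq_len(nc)) {
    r2 <- r + off[1]; c2 <- c + off[2]
    if (r2 >= 1 && r2 <= nr && c2 >= 1 && c2 <= nc)
      p[lvl[r, c], lvl[r2, c2]] <- p[lvl[r, c], lvl[r2, c2]] + 1
  }
  if (symmetric) p <- p + t(p)
  p / sum(p)
}

# brute-force GLCM features by explicit double loops over levels
glcmFeaturesOracle <- function(p) {
  ng <- nrow(p)
  px <- rowSums(p); py <- colSums(p)
  mux <- sum(seq_len(ng) * px); muy <- sum(seq_len(ng) * py)
  sx <- sqrt(sum((seq_len(ng) - mux)^2 * px))
  sy <- sqrt(sum((seq_len(ng) - muy)^2 * py))
  autoc <- 0; contr <- 0; cprom <- 0; cshad <- 0; dissi <- 0
  energy <- 0; entro <- 0; homop <- 0; cor0 <- 0
  for (i in seq_len(ng)) for (j in seq_len(ng)) {
    v <- p[i, j]
    autoc <- autoc + i * j * v
    contr <- contr + (i - j)^2 * v
    cor0 <- cor0 + i * j * v
    cprom <- cprom + (i + j - mux - muy)^4 * v
    cshad <- cshad + (i + j - mux - muy)^3 * v
    dissi <- dissi + abs(i - j) * v
    energy <- energy + v^2
    if (v > 0) entro <- entro - v * log(v)
    homop <- homop + v / (1 + (i - j)^2)
  }
  c(autoc = autoc, contr = contr, corrp = (cor0 - mux * muy) / (sx * sy),
    cprom = cprom, cshad = cshad, dissi = dissi, energy = energy,
    entro = entro, homop = homop, maxpr = max(p))
}

# least squares via explicit pseudo-inverse (SVD), independent of the
# normal-equations route
lsqPinvOracle <- function(Y, R) {
  s <- svd(R)
  s$v %*% diag(1 / s$d, length(s$d)) %*% t(s$u) %*% Y
}

# Dice coefficient computed directly from the overlap definition
diceOracle <- function(a, b) 2 * sum(a & b) / (sum(a > 0) + sum(b > 0))

diceOf <- function(mask, gt) 2 * sum(mask & gt) / (sum(mask) + sum(gt))

bandDeviation <- function(phi, halfWidth = 5) {
  g <- odedema:::gradCentral(phi)
  mag <- sqrt(g$dr^2 + g$dc^2)
  mean(abs(mag[abs(phi) <= halfWidth] - 1))
}

energyViolations <- function(trace, relTol = 1e-3) {
  if (length(trace) < 2L) return(0L)
  sum(diff(trace) > relTol * abs(trace[-length(trace)]))
}

# circle contour points (analytic), for convergence-rule tests
circleContour <- function(center, radius, n = 360) {
  th <- seq(0, 2 * pi, length.out = n + 1)[-(n + 1)]
  cbind(row = center[1] - radius * cos(th),
        col = center[2] + radius * sin(th))
}
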