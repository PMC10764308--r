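# Factorized texture-driven level-set segmentation of the optic disk.
#
# Per-pixel texture is described by local spectral histograms: concatenated
# local histograms of a small filter-bank's responses. The data energy fits
# every pixel's feature vector as a two-column factorization Y ~ R beta,
# where the columns of R are representative object/background features and
# the rows of beta are per-pixel region weights (omega_o, omega_b). The
# contour is the zero level set of phi (phi < 0 inside the disk), evolved by
# explicit gradient descent on
#   E(phi, R) = tau * E_data + upsilon * E_reg,
#   E_data = -sum_x [ H_eps(-phi) omega_o + H_eps(phi) omega_b ],
#   E_reg  = sum_x 0.5 (|grad phi| - 1)^2,
# the second term being the distance-regularization energy that keeps phi
# close to a signed distance function while the contour moves.

# ---- filter bank ------------------------------------------------------------

logKernel <- function(sigma) {
  k <- ceiling(3 * sigma)
  x <- matrix(rep(-k:k, each = 2 * k + 1), 2 * k + 1)
  y <- t(x)
  g <- (x^2 + y^2 - 2 * sigma^2) / sigma^4 * exp(-(x^2 + y^2) / (2 * sigma^2))
  g - mean(g)
}

gaborKernel <- function(sigma, theta, wavelength = 6) {
  k <- ceiling(3 * sigma)
  x <- matrix(rep(-k:k, each = 2 * k + 1), 2 * k + 1)
  y <- t(x)
  xr <- x * cos(theta) + y * sin(theta)
  yr <- -x * sin(theta) + y * cos(theta)
  g <- exp(-(xr^2 + yr^2) / (2 * sigma^2)) * cos(2 * pi * xr / wavelength)
  g - mean(g)
}

fgvfFilterBank <- function() {
  c(list(identity = NULL,
         log1 = logKernel(1), log2 = logKernel(2)),
    stats::setNames(lapply((0:3) * pi / 4, gaborKernel, sigma = 2),
                    paste0("gabor", c(0, 45, 90, 135))))
}

convolveReplicate <- function(m, kern) {
  t(EBImage::filter2(t(m), kern, boundary = "replicate"))
}

# ---- local spectral histograms ---------------------------------------------

#' Local spectral-histogram texture features
#'
#' Applies a 7-band filter bank (identity, Laplacian-of-Gaussian at sigma 1
#' and 2, Gabor at 4 orientations with sigma 2) to a single-channel image
#' and, for every band, computes an 11-bin local histogram over a sliding
#' square window of side \code{max(9, round(h/10))} px (mirror-padded).
#' Stacking the histograms gives the 77 x n feature matrix Y whose columns
#' index the image grid in column-major order.
#'
#' @param img a numeric matrix (the vessel-free ROI)
#' @param bins histogram bins per band
#' @param windowSize odd window side; default \code{max(9, round(nrow/10))}
#' @return list(values = 77 x n matrix, bandNames, windowSize)
#' @export
makeFeatureMatrix <- function(img, bins = 11L, windowSize = NULL) {
  h <- nrow(img); w <- ncol(img)
  if (is.null(windowSize)) windowSize <- max(9L, round(h / 10))
  windowSize <- as.integer(windowSize)
  if (windowSize %% 2L == 0L) windowSize <- windowSize + 1L
  if (windowSize > h || windowSize > w)
    stopf("ROI (%d x %d) smaller than the histogram window (%d)",
          h, w, windowSize)
  k <- (windowSize - 1L) %/% 2L
  bank <- fgvfFilterBank()
  d <- length(bank) * bins
  Y <- matrix(0, d, h * w)
  names <- character(d)
  rowAt <- 0L
  for (b in seq_along(bank)) {
    resp <- if (is.null(bank[[b]])) img else convolveReplicate(img, bank[[b]])
    lo <- min(resp); hi <- max(resp)
    width <- max(hi - lo, 1e-12)
    binIdx <- pmin(floor((resp - lo) / width * bins), bins - 1L) + 1L
    for (q in seq_len(bins)) {
      Y[rowAt + q, ] <- as.numeric(boxMean((binIdx == q) * 1, k))
    }
    names[rowAt + seq_len(bins)] <-
      paste0(names(bank)[b], "_bin", seq_len(bins))
    rowAt <- rowAt + bins
  }
  list(values = Y, bandNames = names, windowSize = windowSize)
}

# ---- level-set machinery ----------------------------------------------------

# Smooth Heaviside / Dirac pair with compact support (the pair used with
# distance-regularized level-set evolution): H rises from 0 to 1 over
# [-eps, eps] with H(0) = 0.5, and delta = H' vanishes for |z| > eps, so
# the data force acts only in a narrow band around the contour and the
# regularization can keep |grad phi| near 1 there.
heavisideEpsFn <- function(z, eps) {
  ifelse(z > eps, 1,
         ifelse(z < -eps, 0,
                0.5 * (1 + z / eps + sin(pi * z / eps) / pi)))
}
deltaEpsFn <- function(z, eps) {
  ifelse(abs(z) > eps, 0, 0.5 / eps * (1 + cos(pi * z / eps)))
}

#' Initialize the level set as a signed distance to a circle
#'
#' phi(x) = |x - center| - radius, negative inside. The default radius is a
#' quarter of the ROI width (see the package vignette for the reading of
#' the initial-circle radius); \code{radius} may be given explicitly.
#'
#' @param shape integer (h, w) of the ROI
#' @param center (row, col) of the seed (the OD location in ROI frame)
#' @param radius circle radius in px; default shape[2] / 4
#' @return list(phi = h x w matrix, iteration = 0)
#' @export
initLevelSet <- function(shape, center, radius = NULL) {
  h <- shape[1]; w <- shape[2]
  if (center[1] < 1 || center[1] > h || center[2] < 1 || center[2] > w)
    stopf("seed (%.1f, %.1f) outside the ROI", center[1], center[2])
  if (is.null(radius)) radius <- w / 4
  rr <- matrix(seq_len(h), h, w)
  cc <- matrix(seq_len(w), h, w, byrow = TRUE)
  phi <- sqrt((rr - center[1])^2 + (cc - center[2])^2) - radius
  list(phi = phi, iteration = 0L)
}

#' Per-pixel region weights from the feature factorization
#'
#' Solves the least-squares factorization beta = argmin ||Y - R beta||^2
#' via the normal equations; omega_o and omega_b are the two rows of beta.
#' A ridge (1e-8 * tr(R'R)/2) is added only when R'R is ill-conditioned;
#' a numerically rank-deficient R (e.g. identical columns) is an error.
#'
#' @param Y feature matrix (d x n) or the list from
#'   \code{\link{makeFeatureMatrix}}
#' @param R d x 2 matrix of representative features (object, background)
#' @return list(omegaO, omegaB (n-vectors), beta (2 x n))
#' @export
computeRegionWeights <- function(Y, R) {
  if (is.list(Y)) Y <- Y$values
  G <- crossprod(R)
  if (!all(is.finite(G)) || rcond(G) < 1e-14)
    stopf("numerical error: representative features are collinear")
  if (rcond(G) < 1e-10)
    G <- G + diag(1e-8 * sum(diag(G)) / 2, 2)
  beta <- solve(G, crossprod(R, Y))
  list(omegaO = beta[1, ], omegaB = beta[2, ], beta = beta)
}

#' Representative features from the current partition
#'
#' The object column is the H_eps(-phi)-weighted mean feature vector, the
#' background column the H_eps(+phi)-weighted mean; a region holding less
#' than 1\% of the soft pixel mass is degenerate.
#'
#' @param Y feature matrix (d x n) or makeFeatureMatrix output
#' @param phi level-set matrix (column-major match with Y's columns)
#' @param heavisideEps width of the smooth Heaviside
#' @return d x 2 matrix with columns (object, background)
#' @export
updateRepresentatives <- function(Y, phi, heavisideEps = 1.5) {
  if (is.list(Y)) Y <- Y$values
  wO <- as.numeric(heavisideEpsFn(-phi, heavisideEps))
  wB <- as.numeric(heavisideEpsFn(phi, heavisideEps))
  n <- length(wO)
  if (sum(wO) < 0.01 * n || sum(wB) < 0.01 * n)
    stopf("degenerate-region error: one region holds <1%% of the pixels")
  cbind(object = as.numeric(Y %*% wO) / sum(wO),
        background = as.numeric(Y %*% wB) / sum(wB))
}

# distance-regularization flow of the (|grad phi| - 1)^2 energy:
# lap(phi) - div(grad phi / |grad phi|)
regularizationFlow <- function(phi) {
  g <- gradCentral(phi)
  mag <- pmax(sqrt(g$dr^2 + g$dc^2), 1e-8)
  nr <- g$dr / mag; nc <- g$dc / mag
  divn <- gradCentral(nr)$dr + gradCentral(nc)$dc
  lap <- gradCentral(g$dr)$dr + gradCentral(g$dc)$dc
  lap - divn
}

#' One explicit evolution step of the level set
#'
#' Gradient descent on the total energy:
#' phi <- phi - dt * tau * delta_eps(phi) * (omega_o - omega_b)
#'            + dt * upsilon * (lap(phi) - div(grad phi / |grad phi|)).
#' Where the object weight exceeds the background weight, phi is pushed
#' negative (into the object), consistent with phi < 0 inside the disk.
#'
#' @param state list(phi, iteration) as from \code{\link{initLevelSet}}
#' @param Y feature matrix or makeFeatureMatrix output
#' @param R representative features (d x 2)
#' @param params an \linkS4class{FGVFParams}
#' @param weights optional precomputed \code{\link{computeRegionWeights}}
#'   output (recomputed from Y and R when missing)
#' @return the updated state
#' @export
evolveStep <- function(state, Y, R, params = fgvfParams(), weights = NULL) {
  phi <- state$phi
  if (is.null(weights)) weights <- computeRegionWeights(Y, R)
  wdiff <- matrix(weights$omegaO - weights$omegaB, nrow(phi), ncol(phi))
  force <- -params@tau * deltaEpsFn(phi, params@heavisideEps) * wdiff +
    params@upsilon * regularizationFlow(phi)
  phi <- phi + params@dt * force
  if (!all(is.finite(phi)))
    stopf("divergence error: non-finite level set (try a smaller dt)")
  list(phi = phi, iteration = state$iteration + 1L)
}

#' Discretized total energy of the current state
#'
#' @inheritParams evolveStep
#' @return named numeric: data, regularization, total
#' @export
fgvfEnergy <- function(state, Y, R, params = fgvfParams(), weights = NULL) {
  phi <- state$phi
  if (is.null(weights)) weights <- computeRegionWeights(Y, R)
  hO <- heavisideEpsFn(-as.numeric(phi), params@heavisideEps)
  hB <- heavisideEpsFn(as.numeric(phi), params@heavisideEps)
  eData <- -sum(hO * weights$omegaO + hB * weights$omegaB)
  g <- gradCentral(phi)
  eReg <- sum(0.5 * (sqrt(g$dr^2 + g$dc^2) - 1)^2)
  c(data = eData, regularization = eReg,
    total = params@tau * eData + params@upsilon * eReg)
}

# ---- contours ---------------------------------------------------------------

#' Extract the zero-level contour of phi
#'
#' Returns the longest zero-level isoline as an ordered (row, col) matrix,
#' or NULL when the zero set is empty.
#'
#' @param phi level-set matrix
#' @return n x 2 matrix of (row, col), or NULL
#' @export
extractContour <- function(phi) {
  cl <- grDevices::contourLines(seq_len(nrow(phi)), seq_len(ncol(phi)),
                                phi, levels = 0)
  if (length(cl) == 0L) return(NULL)
  lens <- vapply(cl, function(z) length(z$x), numeric(1))
  best <- cl[[which.max(lens)]]
  pts <- cbind(row = best$x, col = best$y)
  if (nrow(pts) < 8L) return(NULL)
  pts
}

# resample a closed contour to nOut points by arc length, starting at the
# point nearest to due north of the centroid, oriented counterclockwise in
# (row, col) screen coordinates
resampleContour <- function(pts, nOut = 256L) {
  if (max(abs(pts[1, ] - pts[nrow(pts), ])) > 1e-9)
    pts <- rbind(pts, pts[1, ])
  ctr <- colMeans(pts[-nrow(pts), , drop = FALSE])
  # signed area to fix orientation
  x <- pts[, 2]; y <- pts[, 1]
  area <- sum(x[-length(x)] * y[-1] - x[-1] * y[-length(y)]) / 2
  if (area < 0) pts <- pts[rev(seq_len(nrow(pts))), , drop = FALSE]
  ang <- atan2(pts[-nrow(pts), 2] - ctr[2], -(pts[-nrow(pts), 1] - ctr[1]))
  anchor <- which.min(abs(ang))            # due north: -row direction
  pts <- rbind(pts[anchor:(nrow(pts) - 1L), , drop = FALSE],
               pts[seq_len(anchor), , drop = FALSE])
  seg <- sqrt(rowSums((pts[-1, , drop = FALSE] -
                       pts[-nrow(pts), , drop = FALSE])^2))
  s <- c(0, cumsum(seg))
  total <- s[length(s)]
  if (total <= 0) return(matrix(rep(pts[1, ], each = nOut), nOut))
  at <- seq(0, total, length.out = nOut + 1L)[-(nOut + 1L)]
  cbind(row = stats::approx(s, pts[, 1], xout = at, ties = "ordered")$y,
        col = stats::approx(s, pts[, 2], xout = at, ties = "ordered")$y)
}

#' Contour convergence test
#'
#' Both contours are resampled to 256 arc-length points from a common
#' anchor (the point due north of the centroid); the contour has converged
#' when the mean absolute displacement is below \code{threshold} in both
#' the row and the column direction.
#'
#' @param C,Cprev n x 2 (row, col) contour matrices
#' @param threshold mean displacement threshold in px (default 0.05)
#' @return TRUE or FALSE
#' @export
checkConvergence <- function(C, Cprev, threshold = 0.05) {
  if (is.null(C) || is.null(Cprev) || nrow(C) == 0L || nrow(Cprev) == 0L)
    stopf("convergence error: empty contour (contour collapse)")
  a <- resampleContour(C); b <- resampleContour(Cprev)
  mean(abs(a[, 1] - b[, 1])) < threshold &&
    mean(abs(a[, 2] - b[, 2])) < threshold
}

# ---- driver -----------------------------------------------------------------

#' Segment the optic disk in a vessel-free ROI
#'
#' Full factorized-texture level-set run: build the spectral-histogram
#' feature matrix, initialize phi as a signed distance to a circle around
#' the seed, then alternate representative-feature refreshes with blocks of
#' \code{checkEvery} evolution steps until the contour converges or
#' \code{maxIters} is reached. The returned mask is the phi < 0 region,
#' reduced to its largest connected component with holes filled.
#'
#' @param roi numeric matrix, the vessel-free green channel of the ROI
#' @param seed (row, col) of the OD location in ROI coordinates
#' @param params an \linkS4class{FGVFParams}
#' @param initRadius initial contour radius; default ROI width / 4
#' @return list(mask, contour, diagnostics); diagnostics holds iterations,
#'   converged, energyTrace and the final energy components
#' @export
segmentOD <- function(roi, seed, params = fgvfParams(), initRadius = NULL) {
  Y <- makeFeatureMatrix(roi)
  state <- initLevelSet(dim(roi), seed, radius = initRadius)
  R <- updateRepresentatives(Y, state$phi, params@heavisideEps)
  contourPrev <- extractContour(state$phi)
  energyTrace <- numeric(0)
  converged <- FALSE
  nBlocks <- ceiling(params@maxIters / params@checkEvery)
  for (blk in seq_len(nBlocks)) {
    weights <- computeRegionWeights(Y, R)
    steps <- min(params@checkEvery, params@maxIters - state$iteration)
    for (s in seq_len(steps))
      state <- evolveStep(state, Y, R, params, weights = weights)
    energyTrace <- c(energyTrace,
                     fgvfEnergy(state, Y, R, params, weights)["total"])
    contour <- extractContour(state$phi)
    if (is.null(contour)) {
      stopf("segmentation error: contour collapsed at iteration %d",
            state$iteration)
    }
    if (state$iteration >= params@minIters && !is.null(contourPrev) &&
        checkConvergence(contour, contourPrev, params@convThreshold)) {
      converged <- TRUE
      contourPrev <- contour
      break
    }
    contourPrev <- contour
    # monotone alternating update: adopt the refreshed representatives only
    # when they do not raise the joint energy (guards the energy audit
    # against partition-refresh jumps)
    Rnew <- tryCatch(updateRepresentatives(Y, state$phi,
                                           params@heavisideEps),
                     error = function(e) NULL)
    if (!is.null(Rnew)) {
      eOld <- fgvfEnergy(state, Y, R, params)["total"]
      eNew <- tryCatch(fgvfEnergy(state, Y, Rnew, params)["total"],
                       error = function(e) Inf)
      if (is.finite(eNew) && eNew <= eOld + 1e-3 * abs(eOld)) R <- Rnew
    }
    if (state$iteration >= params@maxIters) break
  }
  mask <- (state$phi < 0) * 1L
  lab <- label8(mask)
  if (max(lab) > 0L) {
    sizes <- tabulate(lab[lab > 0L])
    mask <- (lab == which.max(sizes)) * 1L
    dim(mask) <- dim(state$phi)
    mask <- fillHolesMat(mask)
  }
  finalE <- fgvfEnergy(state, Y, R, params)
  list(mask = mask, contour = contourPrev,
       diagnostics = list(iterations = state$iteration,
                          converged = converged,
                          energyTrace = unname(energyTrace),
                          finalEnergy = finalE,
                          phi = state$phi))
}
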