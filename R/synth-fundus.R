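# Synthetic fundus phantoms with known OD position, OD mask, vessel tree and
# class label. The phantom emulates the appearance contrasts the feature set
# exploits: a bright sharp-edged disk with an inner cup and a complete
# parabolic vessel tree for non-edematous eyes; a larger, blur-edged,
# lower-contrast disk with a fragmented vessel tree for edematous eyes.

# run fn() under a fixed seed without disturbing the caller's RNG stream
withSeed <- function(seed, fn) {
  old <- if (exists(".Random.seed", globalenv(), inherits = FALSE))
    get(".Random.seed", globalenv()) else NULL
  on.exit({
    if (!is.null(old)) assign(".Random.seed", old, globalenv())
    else if (exists(".Random.seed", globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  fn()
}

#' Specify a synthetic fundus phantom
#'
#' Defaults encode the study conditions: the retina nearly fills the frame,
#' a non-edematous optic disk has diameter D/6 (radius fraction 1/12 of the
#' retina diameter D), the disk sits nasally (left of the retina center),
#' and the main vessels form a horizontally opening parabola with vertex at
#' the disk. Edematous phantoms enlarge the disk, blur its edge
#' (\code{edgeBlurSigma >= 3}), lower its contrast against the fundus, and
#' fragment the vessel tree.
#'
#' @param size integer (H, W) of the image
#' @param retinaDiameterFrac retina diameter as a fraction of min(H, W)
#' @param odCenter (row, col) of the disk center; default nasal position
#' @param odRadiusFrac disk radius as a fraction of D; 1/12 gives the
#'   non-edematous D/6 disk diameter
#' @param edgeBlurSigma Gaussian sigma (px) applied to the disk edge
#' @param vesselCompleteness fraction of the vessel tree retained; 1 keeps
#'   the tree connected, lower values delete random gaps
#' @param classLabel "non_edematous" or "edematous"
#' @param rngSeed integer seed; the phantom is a pure function of the spec
#' @return a list with class \code{"PhantomSpec"}
#' @export
phantomSpec <- function(size = c(400L, 400L), retinaDiameterFrac = 0.96,
                        odCenter = NULL, odRadiusFrac = 1 / 12,
                        edgeBlurSigma = 0.8, vesselCompleteness = 1,
                        classLabel = c("non_edematous", "edematous"),
                        rngSeed = 1L) {
  classLabel <- match.arg(classLabel)
  D <- retinaDiameterFrac * min(size)
  ctr <- c(size[1] / 2, size[2] / 2)
  if (is.null(odCenter)) odCenter <- c(ctr[1], ctr[2] - 0.18 * D)
  spec <- list(size = as.integer(size), retinaDiameterFrac = retinaDiameterFrac,
               odCenter = odCenter, odRadiusFrac = odRadiusFrac,
               edgeBlurSigma = edgeBlurSigma,
               vesselCompleteness = vesselCompleteness,
               classLabel = classLabel, rngSeed = as.integer(rngSeed))
  class(spec) <- "PhantomSpec"
  odR <- odRadiusFrac * D
  if (sqrt(sum((odCenter - ctr)^2)) + odR > D / 2)
    stopf("spec error: optic disk does not lie inside the retina")
  spec
}

# stamp a set of (row, col) sample points onto a mask with a given stroke
# radius; points outside the grid are ignored
stampPoints <- function(mask, pts, radius) {
  if (nrow(pts) == 0L) return(mask)
  off <- expand.grid(dr = -ceiling(radius):ceiling(radius),
                     dc = -ceiling(radius):ceiling(radius))
  off <- off[off$dr^2 + off$dc^2 <= radius^2 + 1e-9, , drop = FALSE]
  nr <- nrow(mask); nc <- ncol(mask)
  r <- round(rep(pts[, 1], each = nrow(off)) + off$dr)
  c <- round(rep(pts[, 2], each = nrow(off)) + off$dc)
  ok <- r >= 1 & r <= nr & c >= 1 & c <= nc
  mask[cbind(r[ok], c[ok])] <- 1L
  mask
}

# delete a fraction (1 - keep) of a curve's arc length as contiguous gaps
fragmentCurve <- function(pts, keep, nGaps) {
  n <- nrow(pts)
  if (keep >= 1 || n < 4L) return(list(pts))
  dropLen <- round((1 - keep) * n)
  if (dropLen < 1L) return(list(pts))
  gapLens <- diff(round(seq(0, dropLen, length.out = nGaps + 1L)))
  gapLens <- gapLens[gapLens > 0]
  starts <- sort(sample.int(max(n - max(gapLens), 1L), length(gapLens)))
  keepIdx <- rep(TRUE, n)
  for (i in seq_along(starts))
    keepIdx[seq(starts[i], min(starts[i] + gapLens[i] - 1L, n))] <- FALSE
  runs <- rle(keepIdx)
  out <- list(); pos <- 1L
  for (j in seq_along(runs$lengths)) {
    idx <- seq(pos, pos + runs$lengths[j] - 1L)
    if (runs$values[j] && length(idx) >= 4L) out[[length(out) + 1L]] <- pts[idx, , drop = FALSE]
    pos <- pos + runs$lengths[j]
  }
  out
}

# anisotropic texture: white noise smeared along one axis
orientedTexture <- function(h, w, sigmaAlong, sigmaAcross, horizontal = TRUE) {
  n <- matrix(rnorm(h * w), h, w)
  if (horizontal) {
    n <- t(apply(n, 1L, function(x) gaussSmooth1d(x, sigmaAlong)))
    n <- apply(n, 2L, function(x) gaussSmooth1d(x, sigmaAcross))
  } else {
    n <- apply(n, 2L, function(x) gaussSmooth1d(x, sigmaAlong))
    n <- t(apply(n, 1L, function(x) gaussSmooth1d(x, sigmaAcross)))
  }
  n / max(sd(n), 1e-12)
}

gaussSmooth1d <- function(x, sigma) {
  if (sigma <= 0) return(x)
  k <- ceiling(3 * sigma)
  g <- exp(-(-k:k)^2 / (2 * sigma^2)); g <- g / sum(g)
  n <- length(x)
  xp <- c(rev(x[seq_len(k) + 1L]), x, rev(x)[seq_len(k) + 1L])
  as.numeric(stats::filter(xp, g, sides = 2))[k + seq_len(n)]
}

#' Generate a synthetic fundus phantom
#'
#' Deterministic given the spec (including its seed). See
#' \code{\link{phantomSpec}} for what the two classes look like.
#'
#' @param spec a \code{PhantomSpec} from \code{\link{phantomSpec}}
#' @return a \linkS4class{Phantom}
#' @examples
#' ph <- generatePhantom(phantomSpec(rngSeed = 3))
#' ph
#' @export
generatePhantom <- function(spec) {
  stopifnot(inherits(spec, "PhantomSpec"))
  withSeed(spec$rngSeed, function() .renderPhantom(spec))
}

.renderPhantom <- function(spec) {
  H <- spec$size[1]; W <- spec$size[2]
  D <- spec$retinaDiameterFrac * min(H, W)
  ctr <- c(H / 2, W / 2)
  odC <- spec$odCenter
  odR <- spec$odRadiusFrac * D
  edema <- spec$classLabel == "edematous"

  rr <- matrix(seq_len(H), H, W)
  cc <- matrix(seq_len(W), H, W, byrow = TRUE)
  retina <- ((rr - ctr[1])^2 + (cc - ctr[2])^2) <= (D / 2)^2
  odMask <- ((rr - odC[1])^2 + (cc - odC[2])^2) <= odR^2

  # --- vessel centerlines -----------------------------------------------
  a <- 0.0065 * (D / 384) ^ (-1) * runif(1, 0.85, 1.15)
  drMax <- 0.45 * D
  rows <- seq(odC[1] - drMax, odC[1] + drMax, by = 0.5)
  parab <- cbind(rows, odC[2] + a * (rows - odC[1])^2)
  branchAngles <- c(25, -25, 55, -55) * pi / 180
  branches <- lapply(branchAngles, function(th) {
    t <- seq(0, 0.33 * D, by = 0.5)
    cbind(odC[1] + t * sin(th), odC[2] + t * cos(th))
  })
  nasal <- lapply(c(40, -40) * pi / 180, function(th) {
    t <- seq(0, 0.10 * D, by = 0.5)
    cbind(odC[1] - t * sin(th), odC[2] - t * cos(th))
  })
  daughters <- lapply(c(-0.28, 0.28), function(f) {
    r0 <- odC[1] + f * D
    p0 <- c(r0, odC[2] + a * (f * D)^2)
    th <- atan2(sign(f) * 1, 2 * a * abs(f * D)) + sign(f) * 0.5
    t <- seq(0, 0.09 * D, by = 0.5)
    cbind(p0[1] + t * sin(th), p0[2] + t * cos(th))
  })
  curves <- c(list(parab), branches, nasal, daughters)
  widths <- c(1.5, rep(1.0, 4), rep(0.9, 2), rep(0.9, 2))

  if (spec$vesselCompleteness < 1) {
    frag <- list(); fwid <- numeric(0)
    for (i in seq_along(curves)) {
      pieces <- fragmentCurve(curves[[i]], spec$vesselCompleteness,
                              nGaps = sample(2:4, 1))
      frag <- c(frag, pieces)
      fwid <- c(fwid, rep(widths[i], length(pieces)))
    }
    curves <- frag; widths <- fwid
  }
  vMask <- matrix(0L, H, W)
  for (i in seq_along(curves))
    vMask <- stampPoints(vMask, curves[[i]], widths[i])
  vMask <- vMask * retina

  # --- shading ------------------------------------------------------------
  bgCol <- c(0.60, 0.30, 0.10)
  odCol <- if (edema) c(0.82, 0.52, 0.30) else c(0.97, 0.85, 0.45)
  cupCol <- c(1.00, 0.95, 0.60)
  vesCol <- c(0.28, 0.07, 0.05)

  txBg <- orientedTexture(H, W, sigmaAlong = 6, sigmaAcross = 1.2,
                          horizontal = TRUE)
  txOd <- orientedTexture(H, W, sigmaAlong = 4, sigmaAcross = 0.8,
                          horizontal = FALSE)
  odAlpha <- gaussBlur(odMask * 1, max(spec$edgeBlurSigma, 0.3))
  cupAlpha <- matrix(0, H, W)
  if (!edema) {
    cup <- ((rr - odC[1])^2 + (cc - odC[2])^2) <= (0.38 * odR)^2
    cupAlpha <- gaussBlur(cup * 1, 1.2)
  }
  vAlpha <- gaussBlur(vMask * 1, 0.7)
  vAlpha <- vAlpha / max(vAlpha, 1e-9)

  txAmpBg <- if (edema) 0.035 else 0.032
  txAmpOd <- if (edema) 0.035 else 0.055
  px <- array(0, c(H, W, 3))
  for (ch in 1:3) {
    base <- bgCol[ch] + txAmpBg * txBg
    disk <- odCol[ch] + txAmpOd * txOd
    m <- base * (1 - odAlpha) + disk * odAlpha
    m <- m * (1 - cupAlpha) + (cupCol[ch] + 0.03 * txOd) * cupAlpha
    m <- m * (1 - 0.9 * vAlpha) + vesCol[ch] * (0.9 * vAlpha)
    m[!retina] <- 0.03 + 0.01 * txBg[!retina]
    px[, , ch] <- m
  }
  px <- pmin(pmax(px, 0), 1)

  new("Phantom",
      image = new("FundusImage", pixels = px, path = ""),
      geometry = new("RetinaGeometry", center = ctr, diameter = D),
      odMask = odMask * 1L, vesselMask = vMask,
      odCenter = odC, label = spec$classLabel)
}

#' Two-texture disk fixture for the texture segmenter
#'
#' A disk of one oriented texture on a background of another, with equal
#' texture amplitude and a modest brightness difference — the canonical
#' input for a factorized texture level set. \code{edgeBlurSigma = 0} gives
#' a sharp texture boundary; a positive value cross-fades the two textures
#' over the blurred edge, emulating the blurred margin of an edematous
#' disk.
#'
#' @param rngSeed seed
#' @param edgeBlurSigma Gaussian sigma (px) of the edge cross-fade
#' @param size image side (square)
#' @param radius disk radius in px
#' @param meanObject,meanBackground mean intensities of the two regions
#' @param amplitude texture amplitude (both regions)
#' @return list(image = matrix in [0,1], mask = 0/1 ground-truth disk,
#'   center = c(row, col))
#' @export
textureDiskPhantom <- function(rngSeed, edgeBlurSigma = 0, size = 128L,
                               radius = 32, meanObject = 0.55,
                               meanBackground = 0.45, amplitude = 0.12) {
  withSeed(rngSeed, function() {
    h <- as.integer(size)
    txO <- orientedTexture(h, h, 4, 0.8, horizontal = FALSE)
    txB <- orientedTexture(h, h, 4, 0.8, horizontal = TRUE)
    rr <- matrix(seq_len(h), h, h); cc <- t(rr)
    ctr <- (h + 1) / 2
    disk <- ((rr - ctr)^2 + (cc - ctr)^2) <= radius^2
    alpha <- if (edgeBlurSigma > 0) gaussBlur(disk * 1, edgeBlurSigma)
             else disk * 1
    m <- (meanObject + amplitude * txO) * alpha +
         (meanBackground + amplitude * txB) * (1 - alpha)
    list(image = pmin(pmax(m, 0), 1), mask = disk * 1L,
         center = c(ctr, ctr))
  })
}

#' Generate a labeled cohort of phantoms
#'
#' Draws per-phantom parameters from fixed uniform ranges (edematous: radius
#' fraction U(0.105, 0.135) of D, edge blur U(3, 5) px, vessel completeness
#' U(0.25, 0.45); non-edematous: radius fraction (1/12)*U(0.93, 1.07), edge
#' blur U(0.5, 1.0), complete vessels) with per-phantom seeds derived from
#' the cohort seed.
#'
#' @param nEdema,nNormal numbers of edematous / non-edematous phantoms
#' @param seed cohort seed
#' @param size image size passed to \code{\link{phantomSpec}}
#' @param dir optional directory; when given, images and masks are written
#'   as PNGs and the manifest paths point at them
#' @return list with elements \code{phantoms} (list of
#'   \linkS4class{Phantom}) and \code{manifest} (data.frame)
#' @export
generateCohort <- function(nEdema, nNormal, seed, size = c(400L, 400L),
                           dir = NULL) {
  stopifnot(nEdema >= 0, nNormal >= 0)
  labels <- rep(c("edematous", "non_edematous"), c(nEdema, nNormal))
  n <- length(labels)
  draws <- withSeed(seed, function() {
    data.frame(u1 = runif(n), u2 = runif(n), u3 = runif(n))
  })
  phantoms <- vector("list", n)
  rows <- vector("list", n)
  for (i in seq_len(n)) {
    ede <- labels[i] == "edematous"
    sp <- phantomSpec(
      size = size,
      odRadiusFrac = if (ede) 0.105 + 0.030 * draws$u1[i]
                     else (1 / 12) * (0.93 + 0.14 * draws$u1[i]),
      edgeBlurSigma = if (ede) 3 + 2 * draws$u2[i] else 0.5 + 0.5 * draws$u2[i],
      vesselCompleteness = if (ede) 0.25 + 0.20 * draws$u3[i] else 1,
      classLabel = labels[i],
      rngSeed = (seed %% 100000L) * 10000L + i)
    phantoms[[i]] <- generatePhantom(sp)
    img <- sprintf("phantom_%03d.png", i)
    msk <- sprintf("phantom_%03d_mask.png", i)
    rows[[i]] <- data.frame(image = img, label = labels[i], mask = msk)
  }
  manifest <- do.call(rbind, rows)
  if (!is.null(dir)) {
    if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
    for (i in seq_len(n)) {
      writeMask(phantoms[[i]]@image, file.path(dir, manifest$image[i]))
      writeMask(odMask(phantoms[[i]]), file.path(dir, manifest$mask[i]))
    }
    writeManifest(manifest, file.path(dir, "manifest.csv"))
  }
  list(phantoms = phantoms, manifest = manifest)
}
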