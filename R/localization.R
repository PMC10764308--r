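# Hybrid optic disk localization from the vascular network: the main vessels
# of a complete network trace a horizontally opening parabola whose vertex is
# the OD; a fragmented network is treated as broken straight lines whose
# convergence point is the OD.

#' Segment retinal vessels
#'
#' Multiscale Hessian ridge (vesselness) filter on the green channel at
#' scales 1 and 2 px, tuned for dark vessels on a brighter fundus,
#' hysteresis-thresholded and restricted to the retina region. The skeleton
#' is obtained by morphological thinning and split into segments at branch
#' points.
#'
#' @param img a \linkS4class{FundusImage}
#' @param geometry a \linkS4class{RetinaGeometry}
#' @param scales Gaussian scales (px) of the ridge filter
#' @param highQ,lowQ hysteresis thresholds as quantiles of the vesselness
#'   response inside the retina
#' @return a \linkS4class{VesselMap} (possibly empty)
#' @export
segmentVessels <- function(img, geometry, scales = c(1, 2),
                           highQ = 0.97, lowQ = 0.93) {
  g <- img@pixels[, , 2]
  H <- nrow(g); W <- ncol(g)
  rr <- matrix(seq_len(H), H, W)
  cc <- matrix(seq_len(W), H, W, byrow = TRUE)
  ctr <- geometry@center; D <- geometry@diameter
  retina <- ((rr - ctr[1])^2 + (cc - ctr[2])^2) <= (0.49 * D)^2

  V <- matrix(0, H, W)
  for (s in scales) {
    sm <- gaussBlur(g, s)
    Hrr <- shiftMat(sm, 1L, 0L) + shiftMat(sm, -1L, 0L) - 2 * sm
    Hcc <- shiftMat(sm, 0L, 1L) + shiftMat(sm, 0L, -1L) - 2 * sm
    Hrc <- (shiftMat(sm, 1L, 1L) + shiftMat(sm, -1L, -1L) -
            shiftMat(sm, 1L, -1L) - shiftMat(sm, -1L, 1L)) / 4
    Hrr <- Hrr * s^2; Hcc <- Hcc * s^2; Hrc <- Hrc * s^2
    tmp <- sqrt(((Hrr - Hcc) / 2)^2 + Hrc^2)
    l1 <- (Hrr + Hcc) / 2 - tmp
    l2 <- (Hrr + Hcc) / 2 + tmp
    swap <- abs(l1) > abs(l2)
    t1 <- ifelse(swap, l2, l1); t2 <- ifelse(swap, l1, l2)
    rb2 <- (t1 / pmax(abs(t2), 1e-12))^2
    s2 <- t1^2 + t2^2
    cpar <- max(sqrt(s2)) / 2
    v <- exp(-rb2 / 0.5) * (1 - exp(-s2 / max(2 * cpar^2, 1e-12)))
    v[t2 <= 0] <- 0                     # dark ridges only
    V <- pmax(V, v)
  }
  V[!retina] <- 0
  if (max(V) <= 0)
    return(new("VesselMap", mask = matrix(0L, H, W),
               skeleton = matrix(0L, H, W), segments = list()))
  vals <- V[retina & V > 0]
  hi <- stats::quantile(vals, highQ, names = FALSE)
  lo <- stats::quantile(vals, lowQ, names = FALSE)
  low <- V >= lo
  lab <- label8(low)
  keep <- unique(lab[V >= hi & lab > 0L])
  mask <- (lab %in% keep) * 1L
  dim(mask) <- dim(low)
  if (sum(mask) == 0L)
    return(new("VesselMap", mask = matrix(0L, H, W),
               skeleton = matrix(0L, H, W), segments = list()))
  skel <- thinZS(mask)
  new("VesselMap", mask = mask, skeleton = skel,
      segments = skeletonSegments(skel))
}

# split a skeleton into pixel chains at branch points; each chain is an
# n x 2 (row, col) matrix ordered along the chain
skeletonSegments <- function(skel) {
  if (sum(skel) == 0L) return(list())
  nb <- neighborCount8(skel) * (skel > 0)
  branch <- skel > 0 & nb >= 3
  pruned <- skel * (!branch)
  lab <- label8(pruned)
  ncomp <- max(lab)
  if (ncomp == 0L) return(list())
  nr <- nrow(skel)
  segs <- vector("list", ncomp)
  for (k in seq_len(ncomp)) {
    idx <- which(lab == k)
    pts <- cbind(((idx - 1L) %% nr) + 1L, ((idx - 1L) %/% nr) + 1L)
    segs[[k]] <- orderChain(pts)
  }
  segs
}

# order chain pixels by a nearest-neighbor walk from an extremal point
orderChain <- function(pts) {
  n <- nrow(pts)
  if (n <= 2L) return(pts)
  start <- which.max((pts[, 1] - mean(pts[, 1]))^2 +
                     (pts[, 2] - mean(pts[, 2]))^2)
  left <- rep(TRUE, n); ord <- integer(n)
  cur <- start
  for (i in seq_len(n)) {
    ord[i] <- cur; left[cur] <- FALSE
    if (i == n) break
    cand <- which(left)
    d <- (pts[cand, 1] - pts[cur, 1])^2 + (pts[cand, 2] - pts[cur, 2])^2
    cur <- cand[which.min(d)]
  }
  pts[ord, , drop = FALSE]
}

#' Assess vascular network completeness
#'
#' The network is complete when the largest connected skeleton component
#' spans at least \code{threshold} of the retina diameter horizontally;
#' otherwise it is a collection of broken lines.
#'
#' @param vm a \linkS4class{VesselMap}
#' @param geometry a \linkS4class{RetinaGeometry}
#' @param threshold horizontal span fraction separating complete from
#'   incomplete (default 0.5)
#' @return list(status = "complete"/"incomplete", spanFrac)
#' @export
assessNetwork <- function(vm, geometry, threshold = 0.5) {
  skel <- vm@skeleton
  if (sum(skel) == 0L) stopf("assessment error: empty vessel skeleton")
  lab <- label8(skel)
  sizes <- tabulate(lab[lab > 0L])
  idx <- which(lab == which.max(sizes))
  co <- ((idx - 1L) %/% nrow(skel)) + 1L
  span <- (max(co) - min(co) + 1L) / geometry@diameter
  list(status = if (span >= threshold) "complete" else "incomplete",
       spanFrac = min(span, 1))
}

#' Fit a horizontally opening parabola to skeleton points
#'
#' Least-squares fit of col = a (row - k)^2 + h; the vertex (k, h) is the
#' OD location estimate. The sign of a is free (nasal or temporal opening).
#'
#' @param pts n x 2 matrix of (row, col) points, n >= 3, not collinear
#' @return list(vertex = c(row, col), a)
#' @export
fitParabola <- function(pts) {
  pts <- as.matrix(pts)
  if (nrow(pts) < 3L) stopf("fit error: need at least 3 points")
  r <- pts[, 1]; co <- pts[, 2]
  X <- cbind(r^2, r, 1)
  fit <- tryCatch(qr(X), error = function(e) NULL)
  if (is.null(fit) || fit$rank < 3L)
    stopf("fit error: degenerate design (collinear rows?)")
  beta <- qr.coef(fit, co)
  A <- beta[1]; B <- beta[2]; C <- beta[3]
  if (!is.finite(A) || abs(A) < 1e-10)
    stopf("fit error: degenerate parabola (zero curvature)")
  k <- -B / (2 * A)
  h <- C - B^2 / (4 * A)
  list(vertex = c(row = unname(k), col = unname(h)), a = unname(A))
}

#' Locate the convergence point of broken vessel lines
#'
#' Fits a total-least-squares line to each segment (segments shorter than
#' \code{minLen} pixels are discarded) and returns the point minimizing the
#' sum of squared distances to the fitted lines, by the closed-form normal
#' equations. Because a fragmented arcade also yields fragments whose
#' tangent lines miss the disk, the fit is consensus-based: every pairwise
#' line intersection is scored by how many lines pass within
#' \code{inlierTol} px of it, and the normal equations are solved over the
#' largest consensus set. With up to three lines, or when all lines agree,
#' this reduces to the plain all-lines solution (exact when the lines share
#' a point).
#'
#' @param segments list of n x 2 (row, col) matrices
#' @param minLen minimum segment length in pixels
#' @param inlierTol consensus distance in pixels
#' @return c(row, col)
#' @export
fitLineConvergence <- function(segments, minLen = 10, inlierTol = 15) {
  cands <- convergenceCandidates(segments, minLen, inlierTol)
  best <- cands[[which.max(vapply(cands, function(z)
    z$nInliers - 1e-9 * z$sse, numeric(1)))]]
  c(row = best$point[1], col = best$point[2])
}

# All consensus candidates: for every pairwise line intersection, refit the
# normal equations over the lines within inlierTol of it. Returns a list of
# list(point, nInliers, sse), deduplicated.
convergenceCandidates <- function(segments, minLen = 10, inlierTol = 15) {
  segments <- Filter(function(s) nrow(s) >= max(2L, minLen), segments)
  if (length(segments) < 2L)
    stopf("convergence error: need at least 2 usable segments")
  ns <- length(segments)
  P <- matrix(0, ns, 2); Nrm <- matrix(0, ns, 2)
  for (i in seq_len(ns)) {
    s <- segments[[i]]
    P[i, ] <- colMeans(s)
    e <- eigen(stats::cov(s), symmetric = TRUE)
    dirv <- e$vectors[, 1]
    Nrm[i, ] <- c(-dirv[2], dirv[1])
  }
  solveLines <- function(idx) {
    M <- matrix(0, 2, 2); b <- c(0, 0)
    for (i in idx) {
      Ni <- tcrossprod(Nrm[i, ])
      M <- M + Ni
      b <- b + Ni %*% P[i, ]
    }
    if (rcond(M) < 1e-8) return(NULL)
    as.numeric(solve(M, b))
  }
  lineDist <- function(x)
    abs(Nrm[, 1] * (x[1] - P[, 1]) + Nrm[, 2] * (x[2] - P[, 2]))
  seen <- list(); cands <- list()
  for (i in seq_len(ns - 1L)) for (j in seq(i + 1L, ns)) {
    x <- solveLines(c(i, j))
    if (is.null(x)) next
    d <- lineDist(x)
    inl <- which(d <= inlierTol)
    key <- paste(sort(inl), collapse = ",")
    if (!is.null(seen[[key]])) next
    seen[[key]] <- TRUE
    xr <- solveLines(inl)
    if (is.null(xr)) xr <- x
    dr <- lineDist(xr)
    cands[[length(cands) + 1L]] <-
      list(point = xr, nInliers = length(inl), sse = sum(dr[inl]^2))
  }
  if (length(cands) == 0L)
    stopf("convergence error: all lines (near-)parallel")
  cands
}

#' Localize the optic disk (hybrid method)
#'
#' Segments the vessels, judges network completeness, then dispatches:
#' complete network -> parabola vertex of the largest skeleton component;
#' incomplete -> straight-line convergence point. If both vascular routes
#' fail (e.g. a vessel-free image) the brightest-region centroid is returned
#' with a warning flag. The result is clamped to the retina region.
#'
#' @param img a \linkS4class{FundusImage}
#' @param geometry a \linkS4class{RetinaGeometry}
#' @param completenessThreshold see \code{\link{assessNetwork}}
#' @param vm optional precomputed \linkS4class{VesselMap}
#' @return an \linkS4class{ODLocation}
#' @export
localizeOD <- function(img, geometry, completenessThreshold = 0.5,
                       vm = NULL) {
  if (is.null(vm)) vm <- segmentVessels(img, geometry)
  loc <- NULL; method <- NULL
  ctr <- geometry@center; D <- geometry@diameter
  plausible <- function(p) is.finite(p[1]) && is.finite(p[2]) &&
    sqrt(sum((p - ctr)^2)) <= 0.47 * D
  if (sum(vm@skeleton) > 0L) {
    ass <- assessNetwork(vm, geometry, completenessThreshold)
    if (ass$status == "complete") {
      lab <- label8(vm@skeleton)
      sizes <- tabulate(lab[lab > 0L])
      idx <- which(lab == which.max(sizes))
      nr <- nrow(vm@skeleton)
      pts <- cbind(((idx - 1L) %% nr) + 1L, ((idx - 1L) %/% nr) + 1L)
      fit <- tryCatch(fitParabola(pts), error = function(e) NULL)
      if (!is.null(fit) && plausible(fit$vertex)) {
        loc <- fit$vertex; method <- "parabola"
      }
    }
    if (is.null(loc)) {
      # among strong consensus candidates, prefer the one sitting on the
      # brightest local patch: the disk is the bright convergence target
      cands <- tryCatch(convergenceCandidates(vm@segments),
                        error = function(e) NULL)
      if (!is.null(cands)) {
        ok <- Filter(function(z) z$nInliers >= 3 && plausible(z$point),
                     cands)
        if (length(ok) == 0L)
          ok <- Filter(function(z) plausible(z$point), cands)
        cands <- ok
        if (length(cands)) {
          g <- gaussBlur(toGray(img@pixels), max(D / 30, 1))
          bright <- vapply(cands, function(z) {
            p <- round(z$point)
            g[min(max(p[1], 1), nrow(g)), min(max(p[2], 1), ncol(g))]
          }, numeric(1))
          loc <- cands[[which.max(bright)]]$point
          method <- "convergence"
        }
      }
    }
  }
  warning <- FALSE
  if (is.null(loc)) {
    loc <- brightestCentroid(img, geometry)
    method <- "brightest_fallback"; warning <- TRUE
  }
  loc <- clampToRetina(loc, geometry, dim(img@pixels)[1:2])
  new("ODLocation", center = unname(loc), method = method,
      warning = warning)
}

# centroid of the brightest region inside the retina (adaptive-threshold
# style fallback; never the primary route)
brightestCentroid <- function(img, geometry) {
  g <- gaussBlur(toGray(img@pixels), geometry@diameter / 40)
  H <- nrow(g); W <- ncol(g)
  rr <- matrix(seq_len(H), H, W)
  cc <- matrix(seq_len(W), H, W, byrow = TRUE)
  ctr <- geometry@center
  retina <- ((rr - ctr[1])^2 + (cc - ctr[2])^2) <=
    (0.48 * geometry@diameter)^2
  g[!retina] <- -Inf
  th <- stats::quantile(g[retina], 0.99, names = FALSE)
  m <- g >= th
  lab <- label8(m)
  sizes <- tabulate(lab[lab > 0L])
  idx <- which(lab == which.max(sizes))
  c(mean(((idx - 1L) %% H) + 1L), mean(((idx - 1L) %/% H) + 1L))
}

clampToRetina <- function(loc, geometry, hw) {
  loc <- pmin(pmax(loc, 1), hw)
  ctr <- geometry@center
  d <- sqrt(sum((loc - ctr)^2))
  rmax <- 0.49 * geometry@diameter
  if (d > rmax) loc <- ctr + (loc - ctr) * rmax / d
  loc
}
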