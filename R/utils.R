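# Internal numeric helpers shared across modules. Images are plain numeric
# matrices/arrays indexed [row, col(, channel)], 1-based.

#' @importFrom stats quantile sd rnorm runif
#' @importFrom grDevices convertColor rgb2hsv contourLines
#' @importFrom utils head tail
NULL

# Rec. 601 luma; all "grayscale" reductions in the package go through this.
toGray <- function(rgb) {
  0.299 * rgb[, , 1] + 0.587 * rgb[, , 2] + 0.114 * rgb[, , 3]
}

# RGB array (H x W x 3 in [0,1]) -> Lab array (D65, sRGB gamma assumed)
rgb2lab <- function(rgb) {
  d <- dim(rgb)
  m <- matrix(rgb, ncol = 3L)
  lab <- grDevices::convertColor(m, from = "sRGB", to = "Lab")
  array(lab, dim = d)
}

lab2rgbArr <- function(lab) {
  d <- dim(lab)
  m <- matrix(lab, ncol = 3L)
  rgb <- grDevices::convertColor(m, from = "Lab", to = "sRGB")
  rgb <- pmin(pmax(rgb, 0), 1)
  array(rgb, dim = d)
}

# RGB array -> list(h, s, v) matrices, h in [0, 1)
rgb2hsvArr <- function(rgb) {
  d <- dim(rgb)
  m <- t(matrix(rgb, ncol = 3L))
  hsv <- grDevices::rgb2hsv(m, maxColorValue = 1)
  list(h = matrix(hsv[1, ], d[1], d[2]),
       s = matrix(hsv[2, ], d[1], d[2]),
       v = matrix(hsv[3, ], d[1], d[2]))
}

# shift a matrix by (dr, dc) with replicated (clamped) borders
shiftMat <- function(m, dr, dc) {
  nr <- nrow(m); nc <- ncol(m)
  ri <- pmin(pmax(seq_len(nr) + dr, 1L), nr)
  ci <- pmin(pmax(seq_len(nc) + dc, 1L), nc)
  m[ri, ci, drop = FALSE]
}

# central differences in the interior, one-sided at the borders (so a
# linear field, e.g. a signed distance, has the exact gradient everywhere)
gradCentral <- function(m) {
  nr <- nrow(m); nc <- ncol(m)
  dr <- (shiftMat(m, 1L, 0L) - shiftMat(m, -1L, 0L)) / 2
  dc <- (shiftMat(m, 0L, 1L) - shiftMat(m, 0L, -1L)) / 2
  dr[1, ] <- m[2, ] - m[1, ]; dr[nr, ] <- m[nr, ] - m[nr - 1, ]
  dc[, 1] <- m[, 2] - m[, 1]; dc[, nc] <- m[, nc] - m[, nc - 1]
  list(dr = dr, dc = dc)
}

# central differences with mirror (reflective) borders: the one-sided
# difference at the border evaluates to 0
gradMirror <- function(m) {
  nr <- nrow(m); nc <- ncol(m)
  rp <- c(2L, seq_len(nr), nr - 1L)
  cp <- c(2L, seq_len(nc), nc - 1L)
  p <- m[rp, cp, drop = FALSE]
  list(dr = (p[3:(nr + 2), 2:(nc + 1), drop = FALSE] -
             p[1:nr, 2:(nc + 1), drop = FALSE]) / 2,
       dc = (p[2:(nr + 1), 3:(nc + 2), drop = FALSE] -
             p[2:(nr + 1), 1:nc, drop = FALSE]) / 2)
}

# 5-point Laplacian, replicated borders
laplacian5 <- function(m) {
  shiftMat(m, 1L, 0L) + shiftMat(m, -1L, 0L) +
    shiftMat(m, 0L, 1L) + shiftMat(m, 0L, -1L) - 4 * m
}

# box-filter mean over a (2k+1)^2 window using an integral image,
# mirror-padded so every output window has full support
boxMean <- function(m, k) {
  if (k == 0L) return(m)
  nr <- nrow(m); nc <- ncol(m)
  rp <- c(rev(seq_len(k) + 1L), seq_len(nr), nr - seq_len(k))
  cp <- c(rev(seq_len(k) + 1L), seq_len(nc), nc - seq_len(k))
  p <- m[rp, cp, drop = FALSE]
  s <- apply(apply(p, 2L, cumsum), 1L, cumsum)      # transposed integral
  s <- t(s)
  s <- rbind(0, cbind(0, s))
  w <- 2L * k + 1L
  r1 <- seq_len(nr); c1 <- seq_len(nc)
  (s[r1 + w, c1 + w, drop = FALSE] - s[r1, c1 + w, drop = FALSE] -
     s[r1 + w, c1, drop = FALSE] + s[r1, c1, drop = FALSE]) / (w * w)
}

# Gaussian blur of a matrix via EBImage (expects [x, y] layout internally)
gaussBlur <- function(m, sigma) {
  if (sigma <= 0) return(m)
  t(EBImage::gblur(t(m), sigma = sigma, boundary = "replicate"))
}

# label 8-connected components of a 0/1 matrix; returns integer matrix
# (0 = background). EBImage::bwlabel is 4-connected, hence igraph here.
label8 <- function(mask) {
  idx <- which(mask > 0)
  out <- matrix(0L, nrow(mask), ncol(mask))
  if (length(idx) == 0L) return(out)
  nr <- nrow(mask)
  pos <- seq_along(idx)
  lut <- integer(length(mask)); lut[idx] <- pos
  r <- ((idx - 1L) %% nr) + 1L
  co <- ((idx - 1L) %/% nr) + 1L
  edges <- NULL
  for (d in list(c(1L, 0L), c(0L, 1L), c(1L, 1L), c(1L, -1L))) {
    r2 <- r + d[1]; c2 <- co + d[2]
    ok <- r2 >= 1L & r2 <= nr & c2 >= 1L & c2 <= ncol(mask)
    nidx <- (c2[ok] - 1L) * nr + r2[ok]
    hit <- lut[nidx] > 0L
    if (any(hit))
      edges <- rbind(edges, cbind(pos[ok][hit], lut[nidx][hit]))
  }
  g <- igraph::make_empty_graph(n = length(idx), directed = FALSE)
  if (!is.null(edges)) g <- igraph::add_edges(g, t(edges))
  comp <- igraph::components(g)$membership
  out[idx] <- comp
  out
}

# sizes of 8-connected components, decreasing; integer(0) if empty mask
componentSizes8 <- function(mask) {
  lab <- label8(mask)
  if (max(lab) == 0L) return(integer(0))
  sort(tabulate(lab[lab > 0L]), decreasing = TRUE)
}

# Zhang-Suen thinning of a 0/1 matrix, vectorized over the whole grid
thinZS <- function(mask) {
  m <- mask > 0
  repeat {
    changed <- FALSE
    for (pass in 1:2) {
      p2 <- shiftMat(m, -1L, 0L); p3 <- shiftMat(m, -1L, 1L)
      p4 <- shiftMat(m, 0L, 1L);  p5 <- shiftMat(m, 1L, 1L)
      p6 <- shiftMat(m, 1L, 0L);  p7 <- shiftMat(m, 1L, -1L)
      p8 <- shiftMat(m, 0L, -1L); p9 <- shiftMat(m, -1L, -1L)
      bp <- p2 + p3 + p4 + p5 + p6 + p7 + p8 + p9
      ap <- (!p2 & p3) + (!p3 & p4) + (!p4 & p5) + (!p5 & p6) +
            (!p6 & p7) + (!p7 & p8) + (!p8 & p9) + (!p9 & p2)
      if (pass == 1L) {
        cond <- m & bp >= 2 & bp <= 6 & ap == 1 &
          !(p2 & p4 & p6) & !(p4 & p6 & p8)
      } else {
        cond <- m & bp >= 2 & bp <= 6 & ap == 1 &
          !(p2 & p4 & p8) & !(p2 & p6 & p8)
      }
      # border pixels keep their neighbors replicated; forbid removal there
      cond[1, ] <- FALSE; cond[nrow(m), ] <- FALSE
      cond[, 1] <- FALSE; cond[, ncol(m)] <- FALSE
      if (any(cond)) { m[cond] <- FALSE; changed <- TRUE }
    }
    if (!changed) break
  }
  m * 1L
}

# number of 8-neighbors on a 0/1 matrix, per pixel
neighborCount8 <- function(m) {
  m <- m > 0
  shiftMat(m, -1L, 0L) + shiftMat(m, -1L, 1L) + shiftMat(m, 0L, 1L) +
    shiftMat(m, 1L, 1L) + shiftMat(m, 1L, 0L) + shiftMat(m, 1L, -1L) +
    shiftMat(m, 0L, -1L) + shiftMat(m, -1L, -1L)
}

# fill holes of a 0/1 matrix (EBImage works in [x, y])
fillHolesMat <- function(mask) {
  t(EBImage::fillHull(t(mask * 1))) * 1L
}

stopf <- function(...) stop(sprintf(...), call. = FALSE)
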