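# ROI construction around the localized disk, CLAHE contrast enhancement on
# the L channel of L*a*b*, and vessel removal by harmonic (Laplace-equation)
# inpainting of the green channel.

#' Extract the square region of interest around the optic disk
#'
#' The ROI is a square of side round(D/3) centered at the localized OD
#' (D = retina diameter); an edematous disk is larger than the assumed D/6
#' non-edematous disk diameter, and D/3 accommodates both. Windows reaching
#' past the image border are clipped and flagged.
#'
#' @param img a \linkS4class{FundusImage}
#' @param loc an \linkS4class{ODLocation} (or numeric (row, col))
#' @param geom a \linkS4class{RetinaGeometry}
#' @return an \linkS4class{ROIPatch}
#' @export
extractROI <- function(img, loc, geom) {
  ctr <- if (is(loc, "ODLocation")) loc@center else as.numeric(loc)
  d <- dim(img@pixels)
  if (any(ctr < 1) || ctr[1] > d[1] || ctr[2] > d[2])
    stopf("OD location (%.1f, %.1f) outside the image", ctr[1], ctr[2])
  side <- round(geom@diameter / 3)
  half <- floor(side / 2)
  r0 <- round(ctr[1]) - half; c0 <- round(ctr[2]) - half
  r1 <- r0 + side - 1L; c1 <- c0 + side - 1L
  clipped <- r0 < 1 || c0 < 1 || r1 > d[1] || c1 > d[2]
  r0c <- max(r0, 1L); c0c <- max(c0, 1L)
  r1c <- min(r1, d[1]); c1c <- min(c1, d[2])
  new("ROIPatch", pixels = img@pixels[r0c:r1c, c0c:c1c, , drop = FALSE],
      offset = c(r0c, c0c), widthPx = side, clipped = clipped)
}

#' Contrast-limited adaptive histogram equalization of the ROI
#'
#' Converts the patch to L*a*b* (D65), applies CLAHE to the L channel, and
#' converts back to RGB. A flat field passes through unchanged (up to
#' quantization).
#'
#' @param roi an \linkS4class{ROIPatch}
#' @param tiles CLAHE tile grid (tiles x tiles)
#' @param clipLimit histogram clip limit as a fraction of the tile pixel
#'   count (0.01 clips each bin at 1\% of the tile)
#' @return an \linkS4class{ROIPatch} of the same shape
#' @export
enhanceContrast <- function(roi, tiles = 8, clipLimit = 0.01) {
  lab <- rgb2lab(roi@pixels)
  L <- pmin(pmax(lab[, , 1] / 100, 0), 1)
  lab[, , 1] <- claheMat(L, tiles = tiles, clipLimit = clipLimit) * 100
  out <- roi
  out@pixels <- lab2rgbArr(lab)
  out
}

# Contrast-limited adaptive histogram equalization on a [0,1] matrix:
# per-tile clipped histograms with uniform redistribution of the excess,
# midpoint-rule CDF mapping (a flat field maps to itself up to half a bin),
# and bilinear interpolation between the four surrounding tile mappings.
claheMat <- function(m, tiles = 8, clipLimit = 0.01, bins = 256L) {
  nr <- nrow(m); nc <- ncol(m)
  tiles <- max(1L, min(tiles, nr, nc))
  bin <- pmin(floor(m * bins), bins - 1L) + 1L
  tileR <- pmin(ceiling(row(m) / (nr / tiles)), tiles)
  tileC <- pmin(ceiling(col(m) / (nc / tiles)), tiles)
  maps <- array(0, c(bins, tiles, tiles))
  for (tr in seq_len(tiles)) for (tc in seq_len(tiles)) {
    sel <- tileR == tr & tileC == tc
    h <- tabulate(bin[sel], nbins = bins)
    npx <- sum(h)
    clip <- max(1, clipLimit * npx)
    excess <- sum(pmax(h - clip, 0))
    h <- pmin(h, clip) + excess / bins
    cdf <- cumsum(h)
    maps[, tr, tc] <- (cdf - 0.5 * h) / npx
  }
  # tile centers in pixel coordinates, for the bilinear weights
  ctrR <- (seq_len(tiles) - 0.5) * nr / tiles
  ctrC <- (seq_len(tiles) - 0.5) * nc / tiles
  posR <- row(m); posC <- col(m)
  fr <- pmin(pmax((posR - ctrR[1]) / (nr / tiles), 0), tiles - 1)
  fc <- pmin(pmax((posC - ctrC[1]) / (nc / tiles), 0), tiles - 1)
  r0 <- pmin(floor(fr) + 1L, tiles); r1 <- pmin(r0 + 1L, tiles)
  c0 <- pmin(floor(fc) + 1L, tiles); c1 <- pmin(c0 + 1L, tiles)
  wr <- fr - (r0 - 1L); wc <- fc - (c0 - 1L)
  look <- function(tr, tc) maps[cbind(as.vector(bin), as.vector(tr),
                                      as.vector(tc))]
  v <- (1 - wr) * (1 - wc) * look(r0, c0) + (1 - wr) * wc * look(r0, c1) +
       wr * (1 - wc) * look(r1, c0) + wr * wc * look(r1, c1)
  matrix(pmin(pmax(v, 0), 1), nr, nc)
}

#' Remove vessels from the ROI by harmonic inpainting
#'
#' Takes the green channel of the patch, Gaussian-smooths it outside the
#' vessel mask, then replaces the masked pixels (mask dilated by 1 px to
#' cover anti-aliased vessel edges) with the solution of the discrete
#' Laplace equation, using the unmasked pixels as Dirichlet boundary data.
#' The 5-point stencil makes every filled interior pixel the exact mean of
#' its 4 neighbors, so the fill obeys the discrete maximum principle.
#'
#' @param roi an \linkS4class{ROIPatch}
#' @param vessels 0/1 matrix in the ROI frame (same h x w)
#' @param sigma Gaussian smoothing sigma in px
#' @return h x w numeric matrix: the vessel-free green channel
#' @export
removeVessels <- function(roi, vessels, sigma = 1.5) {
  g <- roi@pixels[, , 2]
  if (!all(dim(vessels) == dim(g)))
    stopf("vessel mask shape %s does not match ROI %s",
          paste(dim(vessels), collapse = "x"),
          paste(dim(g), collapse = "x"))
  g <- gaussBlur(g, sigma)
  if (sum(vessels) == 0L) return(g)
  mask <- EBImage::imageData(EBImage::dilate(
    EBImage::Image(t(vessels * 1)), EBImage::makeBrush(3, "box")))
  mask <- t(mask) > 0
  if (all(mask)) stopf("fill error: mask covers the entire patch")
  laplaceFill(g, mask)
}

# Solve the discrete Laplace equation on masked pixels with Dirichlet data
# from unmasked pixels (sparse direct solve; Neumann at image borders).
laplaceFill <- function(g, mask) {
  nr <- nrow(g); nc <- ncol(g)
  idx <- which(mask)
  n <- length(idx)
  id <- integer(nr * nc); id[idx] <- seq_len(n)
  r <- ((idx - 1L) %% nr) + 1L
  co <- ((idx - 1L) %/% nr) + 1L
  ti <- integer(0); tj <- integer(0); tx <- numeric(0)
  rhs <- numeric(n)
  deg <- numeric(n)
  for (d in list(c(-1L, 0L), c(1L, 0L), c(0L, -1L), c(0L, 1L))) {
    r2 <- r + d[1]; c2 <- co + d[2]
    inb <- r2 >= 1L & r2 <= nr & c2 >= 1L & c2 <= nc
    nidx <- (c2[inb] - 1L) * nr + r2[inb]
    deg[inb] <- deg[inb] + 1
    inner <- id[nidx] > 0L
    # masked neighbor: off-diagonal entry; unmasked: Dirichlet contribution
    ti <- c(ti, which(inb)[inner])
    tj <- c(tj, id[nidx[inner]])
    tx <- c(tx, rep(-1, sum(inner)))
    bidx <- which(inb)[!inner]
    rhs[bidx] <- rhs[bidx] + g[nidx[!inner]]
  }
  A <- Matrix::sparseMatrix(i = c(seq_len(n), ti), j = c(seq_len(n), tj),
                            x = c(deg, tx), dims = c(n, n))
  sol <- as.numeric(Matrix::solve(A, rhs))
  out <- g
  out[idx] <- sol
  out
}
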