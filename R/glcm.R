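# Gray-level co-occurrence matrices and the ten derived texture features.
# Level indices i, j are 1-based throughout (an 0-based convention would
# make autocorrelation degenerate for the lowest level).

#' Gray-level co-occurrence matrix
#'
#' Quantizes a [0,1] image uniformly to \code{levels} gray levels
#' (\code{floor(v * levels)} capped at the top level), counts all in-bounds
#' pixel pairs at each offset, optionally symmetrizes by adding the
#' transpose, and normalizes to sum 1.
#'
#' @param img numeric matrix with values in [0, 1]
#' @param levels number of gray levels N_g
#' @param offsets list of integer c(drow, dcol) displacement vectors;
#'   default the four distance-1 directions (0, 45, 90, 135 degrees)
#' @param symmetric add the transposed counts (default TRUE)
#' @return a list of N_g x N_g normalized matrices, one per offset, each
#'   with attributes mu_x, mu_y, sigma_x, sigma_y
#' @export
computeGLCM <- function(img, levels = 8L,
                        offsets = list(c(0L, 1L), c(-1L, 1L),
                                       c(-1L, 0L), c(-1L, -1L)),
                        symmetric = TRUE) {
  stopifnot(levels >= 2L)
  if (min(img) < 0 || max(img) > 1)
    stopf("GLCM input must lie in [0, 1]")
  lvl <- pmin(floor(img * levels), levels - 1L) + 1L
  nr <- nrow(img); nc <- ncol(img)
  lapply(offsets, function(off) {
    dr <- off[1]; dc <- off[2]
    if (all(off == 0L)) stopf("GLCM offset must be nonzero")
    r1 <- max(1L, 1L - dr):min(nr, nr - dr)
    c1 <- max(1L, 1L - dc):min(nc, nc - dc)
    if (length(r1) < 1L || length(c1) < 1L)
      stopf("image smaller than the GLCM offset")
    i <- lvl[r1, c1, drop = FALSE]
    j <- lvl[r1 + dr, c1 + dc, drop = FALSE]
    counts <- tabulate((j - 1L) * levels + i, nbins = levels * levels)
    p <- matrix(counts, levels, levels)
    if (symmetric) p <- p + t(p)
    if (sum(p) == 0) stopf("no valid pixel pairs at offset")
    p <- p / sum(p)
    ix <- seq_len(levels)
    px <- rowSums(p); py <- colSums(p)
    attr(p, "mu_x") <- sum(ix * px)
    attr(p, "mu_y") <- sum(ix * py)
    attr(p, "sigma_x") <- sqrt(sum((ix - sum(ix * px))^2 * px))
    attr(p, "sigma_y") <- sqrt(sum((ix - sum(ix * py))^2 * py))
    p
  })
}

#' The ten GLCM texture features
#'
#' Autocorrelation, contrast, correlation, cluster prominence, cluster
#' shade, dissimilarity, energy, entropy (natural log, 0 log 0 = 0),
#' homogeneity and maximum probability, each computed exactly from the
#' normalized co-occurrence matrix with 1-based level indices. Correlation
#' is undefined (an error, never silently 0) on a zero-variance matrix.
#'
#' @param p a normalized GLCM from \code{\link{computeGLCM}} (a single
#'   matrix, not the list)
#' @return named numeric of length 10
#' @export
glcmFeatures <- function(p) {
  ng <- nrow(p)
  i <- matrix(seq_len(ng), ng, ng)
  j <- t(i)
  mux <- attr(p, "mu_x"); muy <- attr(p, "mu_y")
  sx <- attr(p, "sigma_x"); sy <- attr(p, "sigma_y")
  if (is.null(mux)) {
    ix <- seq_len(ng); px <- rowSums(p); py <- colSums(p)
    mux <- sum(ix * px); muy <- sum(ix * py)
    sx <- sqrt(sum((ix - mux)^2 * px)); sy <- sqrt(sum((ix - muy)^2 * py))
  }
  if (sx * sy == 0)
    stopf("feature error: correlation undefined (zero variance GLCM)")
  plogp <- ifelse(p > 0, p * log(p), 0)
  c(autoc = sum(i * j * p),
    contr = sum((i - j)^2 * p),
    corrp = (sum(i * j * p) - mux * muy) / (sx * sy),
    cprom = sum((i + j - mux - muy)^4 * p),
    cshad = sum((i + j - mux - muy)^3 * p),
    dissi = sum(abs(i - j) * p),
    energy = sum(p^2),
    entro = -sum(plogp),
    homop = sum(p / (1 + (i - j)^2)),
    maxpr = max(p))
}

#' GLCM features averaged over offsets
#'
#' @inheritParams computeGLCM
#' @return named numeric of length 10 (mean over the offsets)
#' @export
glcmFeatureSet <- function(img, levels = 8L,
                           offsets = list(c(0L, 1L), c(-1L, 1L),
                                          c(-1L, 0L), c(-1L, -1L)),
                           symmetric = TRUE) {
  mats <- computeGLCM(img, levels, offsets, symmetric)
  feats <- vapply(mats, glcmFeatures, numeric(10))
  rowMeans(feats)
}
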