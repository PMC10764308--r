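# Image, mask and manifest I/O plus retina geometry estimation.

#' Load a color fundus photograph
#'
#' Reads a PNG/TIFF/JPEG file into a \linkS4class{FundusImage}. Pixel values
#' are rescaled to \code{[0, 1]} reals (EBImage already divides by the
#' maximum representable value of the on-disk bit depth). Grayscale files are
#' rejected: the pipeline needs all three color channels.
#'
#' @param path path to an image file
#' @return a \linkS4class{FundusImage}
#' @examples
#' f <- tempfile(fileext = ".png")
#' ph <- generatePhantom(phantomSpec(size = c(128, 128)))
#' writeMask(odMask(ph), f)   # any PNG will do for the example
#' @export
loadFundusImage <- function(path) {
  if (!file.exists(path)) stopf("image file not found: %s", path)
  img <- tryCatch(EBImage::readImage(path),
                  error = function(e) stopf("cannot decode image %s: %s",
                                            path, conditionMessage(e)))
  a <- EBImage::imageData(img)
  if (length(dim(a)) == 2L)
    stopf("single-channel image %s: the pipeline requires RGB input", path)
  if (dim(a)[3] > 3L) a <- a[, , 1:3, drop = FALSE]   # drop alpha
  if (dim(a)[3] != 3L)
    stopf("image %s has %d channels; RGB required", path, dim(a)[3])
  px <- aperm(a, c(2L, 1L, 3L))                       # EBImage is [x, y, ch]
  px <- pmin(pmax(px, 0), 1)
  new("FundusImage", pixels = px, path = path)
}

#' @rdname loadFundusImage
#' @param pixels an H x W x 3 array in [0, 1]
#' @export
fundusImage <- function(pixels, path = "") {
  new("FundusImage", pixels = pixels, path = path)
}

#' Write an image or a binary mask to PNG
#'
#' Masks are written as 8-bit 0/255 single-channel PNGs; RGB arrays as
#' 8-bit color PNGs.
#'
#' @param x a 0/1 matrix, an H x W x 3 array, or a \linkS4class{FundusImage}
#' @param path output path (PNG)
#' @return \code{path}, invisibly
#' @export
writeMask <- function(x, path) {
  if (is(x, "FundusImage")) x <- x@pixels
  a <- if (length(dim(x)) == 3L) aperm(x, c(2L, 1L, 3L)) else t(x * 1)
  EBImage::writeImage(EBImage::Image(a,
    colormode = if (length(dim(a)) == 3L) "Color" else "Grayscale"), path)
  invisible(path)
}

#' Read a binary mask PNG
#'
#' @param path PNG path
#' @return a 0/1 integer matrix [row, col]
#' @export
readMask <- function(path) {
  if (!file.exists(path)) stopf("mask file not found: %s", path)
  a <- EBImage::imageData(EBImage::readImage(path))
  if (length(dim(a)) == 3L) a <- a[, , 1]
  (t(a) > 0.5) * 1L
}

#' Estimate the retina's center and diameter
#'
#' The retina diameter D is the pipeline's reference length. The retina is
#' taken as the largest connected foreground component after Otsu
#' thresholding of the per-pixel channel maximum; its centroid is the center
#' and the diameter of its minimum enclosing circle (approximated as twice
#' the maximum centroid-to-foreground distance) is D, capped at min(H, W).
#'
#' @param img a \linkS4class{FundusImage}
#' @return a \linkS4class{RetinaGeometry}
#' @export
estimateRetinaGeometry <- function(img) {
  px <- img@pixels
  mx <- pmax(px[, , 1], px[, , 2], px[, , 3])
  if (max(mx) <= 0) stopf("all-dark image: cannot estimate retina geometry")
  th <- EBImage::otsu(EBImage::Image(t(mx)), range = c(0, 1))
  fg <- mx > th
  if (!any(fg)) stopf("empty foreground: cannot estimate retina geometry")
  lab <- label8(fg)
  sizes <- tabulate(lab[lab > 0L])
  keep <- which.max(sizes)
  idx <- which(lab == keep)
  nr <- nrow(mx)
  r <- ((idx - 1L) %% nr) + 1L
  co <- ((idx - 1L) %/% nr) + 1L
  ctr <- c(mean(r), mean(co))
  # minimum enclosing circle of a centrally-symmetric blob ~ max radius from
  # the centroid; refine once by recentering on the two farthest points
  d2 <- (r - ctr[1])^2 + (co - ctr[2])^2
  diam <- 2 * sqrt(max(d2))
  diam <- min(diam, min(dim(mx)))
  new("RetinaGeometry", center = ctr, diameter = diam)
}

#' @rdname estimateRetinaGeometry
#' @param center numeric (row, col)
#' @param diameter positive scalar, pixels
#' @export
retinaGeometry <- function(center, diameter) {
  new("RetinaGeometry", center = as.numeric(center),
      diameter = as.numeric(diameter))
}

VALID_LABELS <- c("edematous", "non_edematous")

#' Read or write a dataset manifest
#'
#' A manifest is a CSV with header \code{image,label[,mask]} where labels are
#' \code{edematous} or \code{non_edematous}. Read/write round-trips are the
#' identity on valid records.
#'
#' @param path CSV path
#' @return a data.frame with columns image, label and (optionally) mask
#' @export
readManifest <- function(path) {
  if (!file.exists(path)) stopf("manifest not found: %s", path)
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  if (!all(c("image", "label") %in% names(df)))
    stopf("manifest must have columns image,label[,mask]")
  bad <- setdiff(unique(df$label), VALID_LABELS)
  if (length(bad))
    stopf("unknown label(s) in manifest: %s", paste(bad, collapse = ", "))
  if (any(!nzchar(df$image))) stopf("manifest has empty image paths")
  df[, intersect(c("image", "label", "mask", "group"), names(df)),
     drop = FALSE]
}

#' @rdname readManifest
#' @param manifest a manifest data.frame
#' @export
writeManifest <- function(manifest, path) {
  bad <- setdiff(unique(manifest$label), VALID_LABELS)
  if (length(bad))
    stopf("unknown label(s): %s", paste(bad, collapse = ", "))
  utils::write.csv(manifest, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Write a results table as CSV and JSON
#'
#' @param table a data.frame of per-case results
#' @param path output path without extension (".csv" and ".json" are added)
#' @return the two paths, invisibly
#' @export
writeResults <- function(table, path) {
  csv <- paste0(path, ".csv"); js <- paste0(path, ".json")
  utils::write.csv(table, csv, row.names = FALSE)
  jsonlite::write_json(table, js, dataframe = "rows", auto_unbox = TRUE,
                       digits = NA)
  invisible(c(csv, js))
}
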