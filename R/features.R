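# The 27 features fed to the classifier: 10 GLCM texture features, 6 vessel
# features, 7 color features, 4 intensity-line-profile features. Feature
# order is fixed and never depends on input content.

FEATURE_NAMES_27 <- c(
  "autoc", "contr", "corrp", "cprom", "cshad", "dissi", "energy", "entro",
  "homop", "maxpr",
  "vdi", "vdip", "largest_vessel_area", "mean_vessel_area", "sigma",
  "kurtosis",
  "sharpness", "hue", "saturation", "brightness", "mean_intensity",
  "a_star", "b_star",
  "profile_mean", "profile_min", "profile_max", "profile_std")

#' Names of the 27 classifier features, in canonical order
#' @return character vector of length 27
#' @export
featureNames27 <- function() FEATURE_NAMES_27

#' Vessel features
#'
#' Connected components use 8-connectivity. VDI counts the disjoint vessel
#' regions in the ROI (fragmentation indicator, higher under edema); VDIP
#' counts them within the segmented OD region. sigma and kurtosis are the
#' population standard deviation and kurtosis of the ROI gray intensities
#' (kurtosis of a constant image is undefined and raises an error).
#'
#' @param vesselRoi 0/1 matrix, vessels in the ROI frame
#' @param odMaskRoi 0/1 matrix, segmented OD in the ROI frame
#' @param roiGray numeric matrix, ROI gray intensities
#' @return named numeric: vdi, vdip, largest_vessel_area,
#'   mean_vessel_area, sigma, kurtosis
#' @export
vesselFeatures <- function(vesselRoi, odMaskRoi, roiGray) {
  sizes <- componentSizes8(vesselRoi)
  vdi <- length(sizes)
  vdip <- length(componentSizes8(vesselRoi * (odMaskRoi > 0)))
  x <- as.numeric(roiGray)
  mu <- mean(x)
  sigma <- sqrt(mean((x - mu)^2))
  if (sigma == 0)
    stopf("feature error: kurtosis undefined on a constant image")
  kurt <- mean((x - mu)^4) / sigma^4
  c(vdi = vdi, vdip = vdip,
    largest_vessel_area = if (vdi > 0) max(sizes) else 0,
    mean_vessel_area = if (vdi > 0) sum(sizes) / vdi else 0,
    sigma = sigma, kurtosis = kurt)
}

#' Color features of the enhanced ROI
#'
#' Sharpness is the mean Euclidean norm of the central-difference gradient
#' of the gray ROI (mirror borders); hue, saturation and brightness are the
#' means of the HSV channels (hue on [0,1)); a_star and b_star are the
#' means of a* and b* in L*a*b* (D65).
#'
#' @param roi an \linkS4class{ROIPatch} (typically CLAHE-enhanced)
#' @return named numeric: sharpness, hue, saturation, brightness,
#'   mean_intensity, a_star, b_star
#' @export
colorFeatures <- function(roi) {
  px <- roi@pixels
  gray <- toGray(px)
  g <- gradMirror(gray)
  hsv <- rgb2hsvArr(px)
  lab <- rgb2lab(px)
  c(sharpness = mean(sqrt(g$dr^2 + g$dc^2)),
    hue = mean(hsv$h), saturation = mean(hsv$s), brightness = mean(hsv$v),
    mean_intensity = mean(gray),
    a_star = mean(lab[, , 2]), b_star = mean(lab[, , 3]))
}

#' Intensity line-profile features
#'
#' Samples the gray image along a horizontal segment of length round(D/2)
#' centered at the OD location (clipped at the image border with a flag)
#' and returns the mean, min, max and population standard deviation.
#'
#' @param img a \linkS4class{FundusImage}
#' @param loc an \linkS4class{ODLocation} or numeric (row, col)
#' @param geom a \linkS4class{RetinaGeometry}
#' @return named numeric: profile_mean, profile_min, profile_max,
#'   profile_std; attribute "clipped" marks border clipping
#' @export
lineProfileFeatures <- function(img, loc, geom) {
  ctr <- if (is(loc, "ODLocation")) loc@center else as.numeric(loc)
  d <- dim(img@pixels)
  if (ctr[1] < 1 || ctr[1] > d[1] || ctr[2] < 1 || ctr[2] > d[2])
    stopf("OD location outside the image")
  len <- round(geom@diameter / 2)
  cols <- round(ctr[2]) - floor(len / 2) + seq_len(len) - 1L
  clipped <- any(cols < 1L | cols > d[2])
  cols <- cols[cols >= 1L & cols <= d[2]]
  if (length(cols) == 0L) stopf("line profile entirely outside the image")
  gray <- toGray(img@pixels)
  v <- gray[round(ctr[1]), cols]
  out <- c(profile_mean = mean(v), profile_min = min(v),
           profile_max = max(v),
           profile_std = sqrt(mean((v - mean(v))^2)))
  attr(out, "clipped") <- clipped
  out
}

#' Extract the full 27-feature vector for one image
#'
#' GLCM and color features are computed on the contrast-enhanced ROI (gray
#' for GLCM), vessel features on the ROI-frame vessel and OD masks with
#' sigma/kurtosis on the enhanced ROI gray, and the line profile on the
#' full image. Any undefined constituent feature propagates as an error
#' naming the feature; values are never silently imputed.
#'
#' @param img a \linkS4class{FundusImage}
#' @param geom a \linkS4class{RetinaGeometry}
#' @param loc an \linkS4class{ODLocation}
#' @param odMaskRoi 0/1 matrix, segmented OD in the ROI frame
#' @param vm a \linkS4class{VesselMap} (full-image frame)
#' @param roiEnhanced optional precomputed enhanced ROI
#' @param glcmLevels gray levels for the co-occurrence matrix
#' @return named numeric of length 27 in \code{\link{featureNames27}} order
#' @export
extractAllFeatures <- function(img, geom, loc, odMaskRoi, vm,
                               roiEnhanced = NULL, glcmLevels = 8L) {
  roi <- extractROI(img, loc, geom)
  if (is.null(roiEnhanced)) roiEnhanced <- enhanceContrast(roi)
  hw <- dim(roi@pixels)[1:2]
  off <- roi@offset
  vroi <- vm@mask[off[1]:(off[1] + hw[1] - 1L),
                  off[2]:(off[2] + hw[2] - 1L), drop = FALSE]
  if (!all(dim(odMaskRoi) == hw))
    stopf("OD mask (%s) does not match the ROI frame (%s)",
          paste(dim(odMaskRoi), collapse = "x"), paste(hw, collapse = "x"))
  gray <- toGray(roiEnhanced@pixels)
  glcm <- glcmFeatureSet(gray, levels = glcmLevels)
  vessel <- vesselFeatures(vroi, odMaskRoi, gray)
  color <- colorFeatures(roiEnhanced)
  profile <- lineProfileFeatures(img, loc, geom)
  out <- c(glcm, vessel, color, profile)
  attributes(out) <- list(names = FEATURE_NAMES_27)
  if (any(!is.finite(out)))
    stopf("extraction error: non-finite feature(s): %s",
          paste(FEATURE_NAMES_27[!is.finite(out)], collapse = ", "))
  out
}
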