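# End-to-end glue: one case through localize -> ROI -> enhance -> vessel
# removal -> texture level-set segmentation -> features (-> prediction), and
# a cohort experiment producing localization, segmentation and
# classification reports.

#' Run the full pipeline on one image
#'
#' @param img a \linkS4class{FundusImage} or a path to one
#' @param params an \linkS4class{FGVFParams}
#' @param model optional \code{odedemaSVM}; without it the case runs in
#'   feature-only mode
#' @param geom optional \linkS4class{RetinaGeometry} (estimated when
#'   missing)
#' @return list: location, roiOffset, odMaskRoi, odMaskFull, contour,
#'   features, label (or NA), decision, warnings, diagnostics
#' @export
runCase <- function(img, params = fgvfParams(), model = NULL, geom = NULL) {
  if (is.character(img)) img <- loadFundusImage(img)
  stopifnot(is(img, "FundusImage"))
  warnings <- character(0)
  if (is.null(geom)) geom <- estimateRetinaGeometry(img)
  vm <- segmentVessels(img, geom)
  loc <- localizeOD(img, geom, vm = vm)
  if (loc@warning)
    warnings <- c(warnings, "localization fell back to brightest region")
  roi <- extractROI(img, loc, geom)
  if (roi@clipped) warnings <- c(warnings, "ROI clipped at image border")
  hw <- dim(roi@pixels)[1:2]
  off <- roi@offset
  vroi <- vm@mask[off[1]:(off[1] + hw[1] - 1L),
                  off[2]:(off[2] + hw[2] - 1L), drop = FALSE]
  enhanced <- enhanceContrast(roi)
  vesselFree <- removeVessels(roi, vroi)
  seedPt <- pmin(pmax(loc@center - off + 1, 1), hw)
  seg <- segmentOD(vesselFree, seedPt, params)
  full <- matrix(0L, dim(img@pixels)[1], dim(img@pixels)[2])
  full[off[1]:(off[1] + hw[1] - 1L), off[2]:(off[2] + hw[2] - 1L)] <-
    seg$mask
  fv <- extractAllFeatures(img, geom, loc, seg$mask, vm,
                           roiEnhanced = enhanced)
  label <- NA_character_; decision <- NA_real_
  if (!is.null(model)) {
    pr <- predictLabel(model, fv)
    label <- pr$label; decision <- pr$decision
  }
  list(location = loc, roiOffset = off, odMaskRoi = seg$mask,
       odMaskFull = full, contour = seg$contour, features = fv,
       label = label, decision = decision, warnings = warnings,
       diagnostics = seg$diagnostics[c("iterations", "converged")])
}

#' Run the cohort experiment on synthetic phantoms
#'
#' Every phantom goes through the full pipeline; localization is scored
#' against the ground-truth disk (hit iff inside the contour), segmentation
#' pixelwise against the ground-truth mask, and the pooled feature table is
#' classified with a stratified 5-fold linear SVM. Case failures are
#' recorded and skipped; more than 50\% failures aborts the experiment.
#'
#' @param cohort output of \code{\link{generateCohort}} (or a list of
#'   \linkS4class{Phantom})
#' @param seed seed for the cross-validation split
#' @param params an \linkS4class{FGVFParams}
#' @param k folds
#' @return list(localization, segmentation, classification, features,
#'   labels, failures)
#' @export
runExperiment <- function(cohort, seed = 0L, params = fgvfParams(),
                          k = 5L) {
  phantoms <- if (!is.null(cohort$phantoms)) cohort$phantoms else cohort
  n <- length(phantoms)
  hits <- logical(0); segs <- list(); fvs <- list(); labs <- character(0)
  failures <- character(0)
  for (i in seq_len(n)) {
    ph <- phantoms[[i]]
    res <- tryCatch(runCase(ph@image, params = params, geom = ph@geometry),
                    error = function(e) conditionMessage(e))
    if (is.character(res)) {
      failures <- c(failures, sprintf("case %d: %s", i, res))
      next
    }
    hits <- c(hits, scoreLocalization(res$location, ph@odMask))
    segs[[length(segs) + 1L]] <-
      scoreSegmentation(res$odMaskFull, ph@odMask)
    fvs[[length(fvs) + 1L]] <- res$features
    labs <- c(labs, ph@label)
  }
  if (length(failures) > n / 2)
    stopf("experiment error: %d of %d cases failed", length(failures), n)
  X <- do.call(rbind, fvs)
  seg <- list(
    precision = mean(vapply(segs, `[[`, numeric(1), "precision"),
                     na.rm = TRUE),
    recall = mean(vapply(segs, `[[`, numeric(1), "recall"), na.rm = TRUE),
    f1 = mean(vapply(segs, `[[`, numeric(1), "f1"), na.rm = TRUE))
  cls <- if (length(unique(labs)) >= 2L && length(labs) >= k)
    crossValidate(X, labs, k = k, seed = seed) else NULL
  list(localization = localizationAccuracy(hits), segmentation = seg,
       classification = cls, features = X, labels = labs,
       failures = failures)
}
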