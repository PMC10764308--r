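# Scoring: localization accuracy (hit iff the predicted location falls
# inside the ground-truth disk), pixelwise segmentation precision / recall /
# F1, and classification accuracy.

#' Score one localization
#'
#' A localization is correct when the predicted point, rounded to the
#' nearest pixel, lies inside the ground-truth contour (mask value 1).
#'
#' @param pred an \linkS4class{ODLocation} or numeric (row, col)
#' @param gtMask 0/1 ground-truth OD mask
#' @return logical
#' @export
scoreLocalization <- function(pred, gtMask) {
  if (sum(gtMask) == 0L) stopf("empty ground-truth mask")
  ctr <- round(if (is(pred, "ODLocation")) pred@center else as.numeric(pred))
  if (ctr[1] < 1 || ctr[1] > nrow(gtMask) ||
      ctr[2] < 1 || ctr[2] > ncol(gtMask)) return(FALSE)
  gtMask[ctr[1], ctr[2]] == 1
}

#' Aggregate localization hits into Acc_loc = C / N
#'
#' @param hits logical vector of per-image outcomes
#' @return list(nCorrect, nTotal, accLoc)
#' @export
localizationAccuracy <- function(hits) {
  list(nCorrect = sum(hits), nTotal = length(hits),
       accLoc = sum(hits) / length(hits))
}

#' Pixelwise segmentation scores
#'
#' Precision = TP/(TP+FP), Recall = TP/(TP+FN),
#' F1 = 2 P R / (P + R) — algebraically the Dice overlap of the two masks.
#' An empty prediction (TP+FP = 0) leaves precision undefined (NA with a
#' warning), never silently 0; likewise recall for an empty ground truth.
#'
#' @param pred,gt 0/1 masks of identical shape
#' @return list(tp, fp, fn, tn, precision, recall, f1)
#' @export
scoreSegmentation <- function(pred, gt) {
  if (!all(dim(pred) == dim(gt)))
    stopf("mask shape mismatch: %s vs %s",
          paste(dim(pred), collapse = "x"), paste(dim(gt), collapse = "x"))
  p <- pred > 0; g <- gt > 0
  tp <- sum(p & g); fp <- sum(p & !g); fn <- sum(!p & g)
  tn <- sum(!p & !g)
  precision <- if (tp + fp > 0) tp / (tp + fp) else {
    warning("empty prediction: precision undefined"); NA_real_
  }
  recall <- if (tp + fn > 0) tp / (tp + fn) else {
    warning("empty ground truth: recall undefined"); NA_real_
  }
  f1 <- if (!is.na(precision) && !is.na(recall) && precision + recall > 0)
    2 * precision * recall / (precision + recall) else NA_real_
  list(tp = tp, fp = fp, fn = fn, tn = tn,
       precision = precision, recall = recall, f1 = f1)
}

#' Classification accuracy (C_Ede + C_Non) / N
#'
#' @param preds,labels character vectors of equal, nonzero length
#' @return list(cEde, cNon, n, accClassify)
#' @export
scoreClassification <- function(preds, labels) {
  if (length(preds) != length(labels)) stopf("length mismatch")
  if (length(preds) == 0L) stopf("empty prediction vector")
  cEde <- sum(preds == "edematous" & labels == "edematous")
  cNon <- sum(preds == "non_edematous" & labels == "non_edematous")
  list(cEde = cEde, cNon = cNon, n = length(labels),
       accClassify = (cEde + cNon) / length(labels))
}
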