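# Linear SVM classification of the 27-feature vectors, with z-score
# standardization fit on the training rows and stratified k-fold
# cross-validation.

#' Train the linear SVM
#'
#' Standardizes each feature to zero mean and unit variance on the training
#' rows (zero-variance features are dropped with a warning), then fits a
#' linear soft-margin SVM. The stored model applies the same
#' standardization at prediction time, so predictions are invariant to
#' per-feature affine rescalings of the whole table.
#'
#' @param x numeric matrix (rows = samples) or data.frame of features
#' @param labels character/factor with values "edematous" / "non_edematous"
#' @param C soft-margin penalty
#' @param seed integer seed (the fit is deterministic; the seed also guards
#'   any libsvm internal shuffling)
#' @return an object of class \code{odedemaSVM}
#' @export
fitClassifier <- function(x, labels, C = 1.0, seed = 0L) {
  x <- as.matrix(x)
  labels <- as.character(labels)
  if (length(unique(labels)) < 2L)
    stopf("training error: both classes must be present")
  if (!all(labels %in% VALID_LABELS))
    stopf("training error: unknown label(s)")
  if (any(!is.finite(x))) stopf("training error: non-finite features")
  ctr <- colMeans(x)
  scl <- apply(x, 2L, stats::sd)
  keep <- scl > 0
  if (!all(keep))
    warning(sprintf("dropping %d zero-variance feature(s): %s",
                    sum(!keep),
                    paste(colnames(x)[!keep], collapse = ", ")))
  z <- sweep(sweep(x[, keep, drop = FALSE], 2L, ctr[keep]), 2L, scl[keep],
             "/")
  y <- factor(labels, levels = VALID_LABELS)
  fit <- withSeed(seed, function()
    e1071::svm(z, y, kernel = "linear", cost = C, scale = FALSE,
               tolerance = 1e-6))
  w <- drop(crossprod(fit$coefs, fit$SV))
  b <- -fit$rho
  # orient the stored hyperplane so decision > 0 <=> edematous
  dv <- drop(z %*% w + b)
  pred <- ifelse(dv > 0, VALID_LABELS[1], VALID_LABELS[2])
  svmPred <- as.character(stats::predict(fit, z))
  if (mean(pred == svmPred) < 0.5) { w <- -w; b <- -b }
  structure(list(weights = w, bias = b, center = ctr[keep],
                 scale = scl[keep], features = colnames(x)[keep],
                 C = C, seed = seed),
            class = "odedemaSVM")
}

#' @export
print.odedemaSVM <- function(x, ...) {
  cat(sprintf("Linear SVM on %d features (C = %g)\n",
              length(x$weights), x$C))
  invisible(x)
}

#' Predict the disk class for one feature vector
#'
#' Standardized dot product plus bias; a positive decision value means
#' edematous. A decision value of exactly zero is conservatively resolved
#' to non_edematous (ties flagged for review in a prescreening setting).
#'
#' @param model an \code{odedemaSVM}
#' @param fv named numeric feature vector (or matrix of rows)
#' @return list(label, decision)
#' @export
predictLabel <- function(model, fv) {
  if (is.null(dim(fv))) fv <- matrix(fv, 1L, dimnames = list(NULL, names(fv)))
  if (any(!is.finite(fv))) stopf("input error: non-finite feature value")
  cols <- if (!is.null(colnames(fv))) model$features else seq_along(model$features)
  z <- sweep(sweep(fv[, cols, drop = FALSE], 2L, model$center), 2L,
             model$scale, "/")
  d <- drop(z %*% model$weights + model$bias)
  list(label = ifelse(d > 0, VALID_LABELS[1], VALID_LABELS[2]),
       decision = d)
}

# stratified fold assignment: seeded shuffle within class, round-robin
stratifiedFolds <- function(labels, k, seed) {
  folds <- integer(length(labels))
  withSeed(seed, function() {
    for (cl in unique(labels)) {
      idx <- sample(which(labels == cl))
      folds[idx] <<- rep_len(seq_len(k), length(idx))
    }
  })
  folds
}

#' Stratified k-fold cross-validation of the linear SVM
#'
#' Fivefold by default: each fold holds out 20\% for testing and trains on
#' the remaining 80\%. Folds are stratified by class with a seeded shuffle;
#' every sample is tested exactly once and the pooled accuracy is
#' (C_Ede + C_Non) / N.
#'
#' @inheritParams fitClassifier
#' @param k number of folds
#' @return list(foldAccuracies, meanAccuracy, accuracy (pooled),
#'   predictions, confusion = c(cEde, cNon, n))
#' @export
crossValidate <- function(x, labels, k = 5L, C = 1.0, seed = 0L) {
  x <- as.matrix(x)
  labels <- as.character(labels)
  n <- length(labels)
  if (n < k) stopf("split error: fewer samples than folds")
  folds <- stratifiedFolds(labels, k, seed)
  preds <- character(n)
  foldAcc <- numeric(k)
  for (f in seq_len(k)) {
    tr <- folds != f; te <- !tr
    if (length(unique(labels[tr])) < 2L)
      stopf("split error: a training fold lost a class (reduce k)")
    model <- fitClassifier(x[tr, , drop = FALSE], labels[tr], C = C,
                           seed = seed + f)
    preds[te] <- predictLabel(model, x[te, , drop = FALSE])$label
    foldAcc[f] <- mean(preds[te] == labels[te])
  }
  cEde <- sum(preds == "edematous" & labels == "edematous")
  cNon <- sum(preds == "non_edematous" & labels == "non_edematous")
  list(foldAccuracies = foldAcc, meanAccuracy = mean(foldAcc),
       accuracy = (cEde + cNon) / n, predictions = preds,
       confusion = c(cEde = cEde, cNon = cNon, n = n))
}
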