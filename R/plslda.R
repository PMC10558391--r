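#' PLS-LDA classification of Raman spectra
#'
#' Fits the two-stage classifier used throughout the analysis: NIPALS PLS2
#' ([fit_pls()]) compresses the (already preprocessed) spectra against the
#' one-hot class matrix, then linear discriminant analysis ([fit_lda()])
#' finds discriminant directions in the PLS score space. Prediction is
#' nearest class mean in LD space.
#'
#' @param ds a preprocessed [spectral_dataset()]
#' @param n_components number of PLS components (default 10)
#' @param label name of the label column defining the classes (default
#'   `"concentration_mM"`)
#' @return a `plslda_model`: `pls` ([fit_pls()] result), `lda`
#'   ([fit_lda()] result), `levels`, `wavenumbers`, `n_components`, `label`
#' @export
fit_plslda <- function(ds, n_components = 10, label = "concentration_mM") {
  y <- dataset_classes(ds, label)
  if (nlevels(y) < 2) stop("PLS-LDA needs at least two classes")
  X <- t(ds$intensities)
  Y <- stats::model.matrix(~ y - 1)
  pls <- fit_pls(X, Y, n_components)
  lda <- fit_lda(pls$scores, y)
  structure(list(pls = pls, lda = lda, levels = levels(y),
                 wavenumbers = ds$wavenumbers,
                 n_components = pls$n_components, label = label),
            class = "plslda_model")
}

dataset_classes <- function(ds, label) {
  if (!label %in% names(ds$labels))
    stop(sprintf("label column '%s' not found in dataset labels", label))
  factor(ds$labels[[label]])
}

#' @rdname fit_plslda
#' @param object a `plslda_model`
#' @param newdata a [spectral_dataset()] or spectra matrix (rows =
#'   observations) on the training axis
#' @param ... unused
#' @return `predict()` returns a factor of predicted classes.
#' @export
predict.plslda_model <- function(object, newdata, ...) {
  X <- if (inherits(newdata, "spectral_dataset")) t(newdata$intensities)
       else as.matrix(newdata)
  predict(object$lda, pls_scores(object$pls, X))
}

#' Stratified k-fold cross-validation of PLS-LDA
#'
#' Splits each class separately into `k` folds (shuffled with `seed`,
#' assigned round-robin so fold sizes differ by at most one per class),
#' fits PLS-LDA on the training part of each fold — all data-dependent
#' statistics, including centring, are computed inside the fold — and
#' pools the out-of-fold predictions into one confusion matrix. Per-fold
#' accuracies are also reported, with their fold-size-weighted mean equal
#' to the pooled accuracy.
#'
#' @param ds a preprocessed [spectral_dataset()]
#' @param k number of folds (default 5); every class must have >= k members
#' @param n_components PLS components per fold model
#' @param seed integer seed for the fold shuffle
#' @param label class label column
#' @return a `cv_report`: `k`, `confusion` (rows = true class, columns =
#'   predicted), `sensitivity`, `specificity`, `accuracy`,
#'   `fold_accuracy`, `fold_assignments`, `n_components`
#' @export
kfold_cv <- function(ds, k = 5, n_components = 10, seed = 0,
                     label = "concentration_mM") {
  y <- dataset_classes(ds, label)
  counts <- table(y)
  if (any(counts < k))
    stop(sprintf("every class needs at least k = %d members (smallest has %d)",
                 k, min(counts)))
  set.seed(seed)
  fold <- integer(length(y))
  for (lv in levels(y)) {
    idx <- sample(which(y == lv))
    fold[idx] <- rep_len(seq_len(k), length(idx))
  }
  pred <- factor(rep(NA_character_, length(y)), levels = levels(y))
  for (f in seq_len(k)) {
    train <- fold != f
    sub <- spectral_dataset(ds$wavenumbers,
                            ds$intensities[, train, drop = FALSE],
                            ds$labels[train, , drop = FALSE])
    model <- fit_plslda(sub, n_components, label)
    pred[!train] <- predict(model, t(ds$intensities[, !train, drop = FALSE]))
  }
  confusion <- table(true = y, predicted = pred)
  metrics <- confusion_metrics(confusion)
  fold_acc <- vapply(seq_len(k), function(f)
    mean(pred[fold == f] == y[fold == f]), numeric(1))
  structure(list(k = k, confusion = confusion,
                 sensitivity = metrics$sensitivity,
                 specificity = metrics$specificity,
                 accuracy = metrics$accuracy,
                 fold_accuracy = fold_acc,
                 fold_assignments = fold,
                 n_components = n_components),
            class = "cv_report")
}

#' @export
print.cv_report <- function(x, ...) {
  cat(sprintf("<%d-fold CV: accuracy %.1f%%>\n", x$k, 100 * x$accuracy))
  print(x$confusion)
  invisible(x)
}

#' Per-class sensitivity, specificity and overall accuracy
#'
#' For a confusion matrix with rows = true classes and columns = predicted
#' classes: `sensitivity_c = TP_c / (TP_c + FN_c)` (the diagonal over the
#' row sum), `specificity_c = TN_c / (TN_c + FP_c)`, and
#' `accuracy = trace / total`. A class with no true members has undefined
#' sensitivity, reported as `NA` with a warning.
#'
#' @param confusion square matrix of non-negative counts
#' @return list with `sensitivity`, `specificity` (named per class) and
#'   `accuracy`
#' @export
confusion_metrics <- function(confusion) {
  m <- as.matrix(confusion)
  if (nrow(m) != ncol(m) || any(m < 0)) stop("confusion must be a square non-negative matrix")
  total <- sum(m)
  tp <- diag(m)
  rs <- rowSums(m)
  cs <- colSums(m)
  if (any(rs == 0))
    warning("class(es) with no true members: sensitivity undefined (NA)")
  sens <- ifelse(rs > 0, tp / rs, NA_real_)
  tn <- total - rs - cs + tp
  fp <- cs - tp
  spec <- ifelse(tn + fp > 0, tn / (tn + fp), NA_real_)
  nm <- rownames(m)
  names(sens) <- nm; names(spec) <- nm
  list(sensitivity = sens, specificity = spec, accuracy = sum(tp) / total)
}

#' Discriminant loading spectra
#'
#' Back-projects each LD direction from PLS score space onto the original
#' wavenumber axis: the loading is `R d`, where `R` is the PLS rotation
#' (scores = centred spectra times `R`) and `d` the LD direction, so the LD
#' score of a spectrum is its centred intensity vector dotted with the
#' loading. Sign convention: each loading's largest-magnitude element is
#' made positive, so loadings are reproducible under arbitrary sign flips
#' of the eigenvectors.
#'
#' @param model a fitted `plslda_model`
#' @return an `ld_loading_spectrum`: `wavenumbers` plus a `loadings` matrix
#'   with one column per discriminant (LD1, LD2, ...)
#' @export
ld_loadings <- function(model) {
  L <- model$pls$rotation %*% model$lda$scalings
  for (j in seq_len(ncol(L))) {
    i <- which.max(abs(L[, j]))
    if (L[i, j] < 0) L[, j] <- -L[, j]
  }
  colnames(L) <- paste0("LD", seq_len(ncol(L)))
  structure(list(wavenumbers = model$wavenumbers, loadings = L),
            class = "ld_loading_spectrum")
}
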