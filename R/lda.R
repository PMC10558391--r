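#' Linear discriminant analysis in PLS score space
#'
#' Fisher's multi-class LDA: solves the generalized eigenproblem of the
#' between-class scatter against the pooled within-class scatter via a
#' Cholesky-whitened symmetric eigendecomposition. At most
#' `n_classes - 1` discriminant directions are returned, ordered by
#' decreasing eigenvalue and scaled to unit norm. For two classes LD1 is
#' proportional to the Fisher closed form `Sw^{-1} (m1 - m2)`.
#'
#' If the within-class scatter is (numerically) singular it is
#' ridge-regularized by `ridge * mean(diag(Sw)) * I` with a warning.
#'
#' @param scores numeric matrix, rows = observations (e.g. PLS scores)
#' @param labels factor (or coercible) of class labels, >= 2 classes with
#'   >= 2 observations each
#' @param ridge relative ridge used only when `Sw` is singular
#' @return an `lda_model`: `scalings` (columns = unit-norm LD directions),
#'   `eigenvalues`, `class_means` (in LD space), `levels`, `priors`
#' @export
fit_lda <- function(scores, labels, ridge = 1e-8) {
  scores <- as.matrix(scores)
  labels <- factor(labels)
  if (nlevels(labels) < 2) stop("LDA needs at least two classes")
  counts <- table(labels)
  if (any(counts < 2)) stop("every class needs at least two observations")
  n <- nrow(scores); d <- ncol(scores); k <- nlevels(labels)
  grand <- colMeans(scores)
  Sw <- matrix(0, d, d)
  Sb <- matrix(0, d, d)
  mus <- matrix(0, k, d)
  for (j in seq_len(k)) {
    Xi <- scores[labels == levels(labels)[j], , drop = FALSE]
    mu <- colMeans(Xi)
    mus[j, ] <- mu
    Xi <- sweep(Xi, 2, mu)
    Sw <- Sw + crossprod(Xi)
    dm <- mu - grand
    Sb <- Sb + nrow(Xi) * tcrossprod(dm)
  }
  Sw <- Sw / (n - k)
  ch <- tryCatch(chol(Sw), error = function(e) NULL)
  if (is.null(ch)) {
    warning("singular within-class scatter: applying ridge regularization")
    Sw <- Sw + ridge * mean(diag(Sw)) * diag(d)
    ch <- chol(Sw)
  }
  # whiten: Sw = C'C; solve eig of inv(C') Sb inv(C), back-transform
  Ci <- backsolve(ch, diag(d))
  M <- t(Ci) %*% Sb %*% Ci
  M <- (M + t(M)) / 2
  eg <- eigen(M, symmetric = TRUE)
  m <- min(k - 1, d)
  V <- Ci %*% eg$vectors[, seq_len(m), drop = FALSE]
  V <- sweep(V, 2, sqrt(colSums(V^2)), `/`)
  structure(list(scalings = V,
                 eigenvalues = eg$values[seq_len(m)],
                 class_means = mus %*% V,
                 levels = levels(labels),
                 priors = as.numeric(counts) / n),
            class = "lda_model")
}

#' Classify observations with a fitted LDA model
#'
#' Projects observations onto the discriminant directions and assigns the
#' nearest class mean (Euclidean distance in LD space). Ties are broken in
#' favour of the lowest class index.
#'
#' @param object an `lda_model`
#' @param newdata score matrix on the same axis the model was fitted on
#' @param ... unused
#' @return factor of predicted classes
#' @export
predict.lda_model <- function(object, newdata, ...) {
  Z <- as.matrix(newdata) %*% object$scalings
  M <- object$class_means
  d2 <- outer(rowSums(Z^2), rowSums(M^2), `+`) - 2 * Z %*% t(M)
  idx <- apply(d2, 1, which.min)  # which.min takes the first (lowest) index on ties
  factor(object$levels[idx], levels = object$levels)
}
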