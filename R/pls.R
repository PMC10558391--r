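#' Partial least squares (NIPALS PLS2)
#'
#' From-scratch NIPALS implementation of PLS2 for a multi-column response
#' (here the one-hot class indicator matrix). Predictors and responses are
#' column-centred internally; no variance scaling is applied, since input
#' spectra are already band-normalized. Components are extracted by the
#' classical NIPALS iteration (weight w from the X-side regression on the
#' y-score u, score t = X w, deflation of X by the loading p and of Y by
#' its regression on t). Successive training-score vectors are orthogonal.
#'
#' Prediction uses the rotation `R = W (P' W)^{-1}`, which maps centred new
#' observations directly to component scores: `T = (X - x_mean) R`.
#'
#' @param X numeric matrix, rows = observations (spectra), columns =
#'   features (wavenumbers)
#' @param Y numeric response matrix, rows matching `X` (one-hot class
#'   indicators for classification)
#' @param n_components number of latent components, between 1 and
#'   `min(nrow(X) - 1, ncol(X))`
#' @param tol NIPALS convergence tolerance on the score vector
#' @param max_iter NIPALS iteration cap per component
#' @return a `pls_model`: `weights` (W), `loadings` (P), `rotation` (R),
#'   `x_mean`, `scores` (training T), `n_components` (actually extracted;
#'   fewer than requested if deflation exhausts X, with a warning)
#' @export
fit_pls <- function(X, Y, n_components, tol = 1e-10, max_iter = 500) {
  X <- as.matrix(X); Y <- as.matrix(Y)
  stopifnot(nrow(X) == nrow(Y))
  n <- nrow(X); p <- ncol(X)
  if (n_components < 1 || n_components > min(n - 1, p))
    stop("n_components must be between 1 and min(n_samples - 1, n_features)")
  x_mean <- colMeans(X)
  y_mean <- colMeans(Y)
  Xc <- sweep(X, 2, x_mean)
  Yc <- sweep(Y, 2, y_mean)
  W <- matrix(0, p, n_components)
  P <- matrix(0, p, n_components)
  Tm <- matrix(0, n, n_components)
  a <- 0L
  for (k in seq_len(n_components)) {
    # start u from the Y column with the largest variance
    u <- Yc[, which.max(apply(Yc, 2, stats::var))]
    if (all(abs(u) < tol)) break
    t_old <- rep(Inf, n)
    for (it in seq_len(max_iter)) {
      w <- crossprod(Xc, u)
      nw <- sqrt(sum(w^2))
      if (nw < tol) break
      w <- w / nw
      tt <- as.numeric(Xc %*% w)
      q <- crossprod(Yc, tt)
      nq <- sqrt(sum(q^2))
      if (nq < tol) break
      q <- q / nq
      u <- as.numeric(Yc %*% q)
      if (sqrt(sum((tt - t_old)^2)) < tol * sqrt(sum(tt^2))) break
      t_old <- tt
    }
    w <- crossprod(Xc, u)
    nw <- sqrt(sum(w^2))
    if (nw < tol) {
      warning(sprintf("NIPALS deflation collapsed: extracted %d of %d components",
                      a, n_components))
      break
    }
    w <- w / nw
    tt <- as.numeric(Xc %*% w)
    tsq <- sum(tt^2)
    if (tsq < tol) {
      warning(sprintf("NIPALS deflation collapsed: extracted %d of %d components",
                      a, n_components))
      break
    }
    pv <- crossprod(Xc, tt) / tsq
    cv <- crossprod(Yc, tt) / tsq
    Xc <- Xc - tcrossprod(tt, pv)
    Yc <- Yc - tcrossprod(tt, cv)
    a <- a + 1L
    W[, a] <- w; P[, a] <- pv; Tm[, a] <- tt
  }
  if (a == 0L) stop("no PLS component could be extracted")
  W <- W[, seq_len(a), drop = FALSE]
  P <- P[, seq_len(a), drop = FALSE]
  Tm <- Tm[, seq_len(a), drop = FALSE]
  R <- W %*% solve(crossprod(P, W))
  structure(list(weights = W, loadings = P, rotation = R,
                 x_mean = x_mean, y_mean = y_mean, scores = Tm,
                 n_components = a),
            class = "pls_model")
}

#' Component scores of new observations under a fitted PLS model
#' @param model a `pls_model`
#' @param X matrix of observations on the training feature axis
#' @return numeric score matrix, one row per observation
#' @export
pls_scores <- function(model, X) {
  X <- if (is.null(dim(X))) matrix(X, nrow = 1) else as.matrix(X)
  sweep(X, 2, model$x_mean) %*% model$rotation
}
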