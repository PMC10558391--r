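# Independent least-squares oracle: Moore-Penrose pseudoinverse via SVD,
# deliberately a different route than the package's QR solve.
pinv_solve <- function(D, y, tol = 1e-12) {
  sv <- svd(D)
  pos <- sv$d > tol * max(sv$d)
  sv$v[, pos, drop = FALSE] %*%
    ((t(sv$u[, pos, drop = FALSE]) %*% y) / sv$d[pos])
}

# Fisher two-class discriminant closed form: d = Sw^-1 (m1 - m2)
fisher_direction <- function(X, y) {
  y <- factor(y)
  stopifnot(nlevels(y) == 2)
  X1 <- X[y == levels(y)[1], , drop = FALSE]
  X2 <- X[y == levels(y)[2], , drop = FALSE]
  Sw <- (crossprod(sweep(X1, 2, colMeans(X1))) +
         crossprod(sweep(X2, 2, colMeans(X2)))) / (nrow(X) - 2)
  d <- solve(Sw, colMeans(X1) - colMeans(X2))
  d / sqrt(sum(d^2))
}

# cosine of the angle between two directions, sign-insensitive
abs_cosine <- function(a, b) abs(sum(a * b)) / sqrt(sum(a^2) * sum(b^2))

# small, fast image config for tests
tiny_image_cfg <- function(seed = 1, ...) {
  image_gen_config(size_px = 160, seed = seed, ...)
}
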