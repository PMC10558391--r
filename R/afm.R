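#' Topography flattening operators
#'
#' Standard AFM background-removal steps, mirroring the usual processing
#' order for intermittent-contact scans of tissue: least-squares plane
#' subtraction ([plane_flatten()]), per-scan-line offset removal
#' ([line_flatten()]), full second-order polynomial background subtraction
#' ([poly2_flatten()]) and setting the minimum height to zero
#' ([zero_min()]). [flatten_topography()] chains them in a configurable
#' order. All operators are idempotent.
#'
#' @param t a [topography()]
#' @return a flattened [topography()]
#' @export
plane_flatten <- function(t) {
  h <- t$heights
  nr <- nrow(h); nc <- ncol(h)
  if (nr * nc < 3) stop("need at least 3 pixels to fit a plane")
  xi <- rep(seq_len(nc) - 1, each = nr)
  yi <- rep(seq_len(nr) - 1, times = nc)
  fit <- stats::lm.fit(cbind(1, xi, yi), as.numeric(h))
  topography(matrix(stats::residuals(fit), nr, nc), t$pixel_nm, t$meta)
}

#' @rdname plane_flatten
#' @param method `"median"` (default; robust to fibril crests) or `"mean"`
#' @export
line_flatten <- function(t, method = c("median", "mean")) {
  method <- match.arg(method)
  stat <- if (method == "median") function(r) stats::median(r) else mean
  offs <- apply(t$heights, 1, stat)
  topography(t$heights - offs, t$pixel_nm, t$meta)
}

#' @rdname plane_flatten
#' @export
poly2_flatten <- function(t) {
  h <- t$heights
  nr <- nrow(h); nc <- ncol(h)
  if (nr * nc < 6) stop("need at least 6 pixels for a quadratic surface fit")
  # centred, scaled coordinates keep the quadratic design well conditioned
  xi <- rep(seq_len(nc) - 1, each = nr); xi <- (xi - mean(xi)) / max(1, nc - 1)
  yi <- rep(seq_len(nr) - 1, times = nc); yi <- (yi - mean(yi)) / max(1, nr - 1)
  X <- cbind(1, xi, yi, xi^2, xi * yi, yi^2)
  fit <- stats::lm.fit(X, as.numeric(h))
  if (fit$rank < 6) stop("rank-deficient quadratic design")
  topography(matrix(stats::residuals(fit), nr, nc), t$pixel_nm, t$meta)
}

#' @rdname plane_flatten
#' @export
zero_min <- function(t) {
  topography(t$heights - min(t$heights), t$pixel_nm, t$meta)
}

#' @rdname plane_flatten
#' @param steps character vector of steps to apply in order, from
#'   `"plane"`, `"line"`, `"poly2"`, `"zero"`
#' @export
flatten_topography <- function(t, steps = c("plane", "line", "poly2", "zero")) {
  for (s in steps) {
    t <- switch(s,
                plane = plane_flatten(t),
                line = line_flatten(t),
                poly2 = poly2_flatten(t),
                zero = zero_min(t),
                stop(sprintf("unknown flattening step '%s'", s)))
  }
  t$meta$flatten_steps <- steps
  t
}

#' RMS surface roughness (second central moment)
#'
#' `sqrt(mean((h - mean(h))^2))` over all pixels — the population second
#' central moment (divisor N), as appropriate within one image. Invariant
#' under adding any constant, so [zero_min()] does not change it. The
#' input is expected to be flattened first (not enforced).
#'
#' @param t a [topography()]
#' @return roughness in nm
#' @export
rms_roughness <- function(t) {
  h <- t$heights
  sqrt(mean((h - mean(h))^2))
}

#' Roughness summary over an image set
#'
#' Per-image RMS roughness plus the mean and sample standard deviation
#' (divisor n - 1) across images — the image-set statistic reported for
#' repeated scans of one sample.
#'
#' @param ts list of >= 2 [topography()] objects
#' @return a `roughness_result`: `rms_nm` (per image), `mean_nm`, `sd_nm`
#' @export
roughness_summary <- function(ts) {
  if (length(ts) < 2) stop("need at least 2 images for a set summary (sd undefined)")
  rms <- vapply(ts, rms_roughness, numeric(1))
  structure(list(rms_nm = rms, mean_nm = mean(rms), sd_nm = stats::sd(rms)),
            class = "roughness_result")
}

#' Extract a height profile along a polyline
#'
#' Samples the surface by bilinear interpolation at a spacing of
#' `pixel_nm / 2` along the polyline. Endpoints are given in nm (pixel
#' centres at integer indices, position = index * pixel_nm); positions in
#' the output run from 0 at the first vertex.
#'
#' @param t a [topography()]
#' @param endpoints_nm numeric matrix with one `(x, y)` row per polyline
#'   vertex, in nm (x = along columns, y = along rows)
#' @return a `line_profile`: `positions` (nm from the start) and `heights`
#'   (nm)
#' @export
extract_profile <- function(t, endpoints_nm) {
  endpoints_nm <- matrix(as.numeric(endpoints_nm), ncol = 2)
  if (nrow(endpoints_nm) < 2) stop("polyline needs at least two vertices")
  px <- endpoints_nm / t$pixel_nm
  nx <- ncol(t$heights); ny <- nrow(t$heights)
  if (any(px[, 1] < 0) || any(px[, 1] > nx - 1) ||
      any(px[, 2] < 0) || any(px[, 2] > ny - 1))
    stop("polyline extends outside the image")
  step <- t$pixel_nm / 2
  pos <- numeric(0); hei <- numeric(0); offset <- 0
  for (seg in seq_len(nrow(endpoints_nm) - 1)) {
    a <- endpoints_nm[seg, ]; b <- endpoints_nm[seg + 1, ]
    len <- sqrt(sum((b - a)^2))
    ss <- seq(0, len, by = step)
    if (ss[length(ss)] < len) ss <- c(ss, len)
    if (seg > 1) ss <- ss[-1]  # drop duplicated vertex
    xs <- (a[1] + (b[1] - a[1]) * ss / len) / t$pixel_nm
    ys <- (a[2] + (b[2] - a[2]) * ss / len) / t$pixel_nm
    hei <- c(hei, bilinear_at(t$heights, xs, ys))
    pos <- c(pos, offset + ss)
    offset <- offset + len
  }
  structure(list(positions = pos, heights = hei), class = "line_profile")
}

# bilinear interpolation at fractional 0-based pixel coordinates
# (x along columns, y along rows)
bilinear_at <- function(h, x, y) {
  nx <- ncol(h); ny <- nrow(h)
  x0 <- pmin(floor(x), nx - 2); x0 <- pmax(x0, 0)
  y0 <- pmin(floor(y), ny - 2); y0 <- pmax(y0, 0)
  fx <- x - x0; fy <- y - y0
  i <- function(r, c) h[cbind(r + 1, c + 1)]
  (1 - fx) * (1 - fy) * i(y0, x0) + fx * (1 - fy) * i(y0, x0 + 1) +
    (1 - fx) * fy * i(y0 + 1, x0) + fx * fy * i(y0 + 1, x0 + 1)
}

# Local maxima with topographic prominence. A peak's prominence is its
# height minus the higher of the two minima separating it from higher
# terrain (or from the signal ends). Peaks are then thinned by minimum
# separation, keeping higher peaks first.
find_crests <- function(y, min_prominence = 0, min_separation_idx = 1) {
  n <- length(y)
  if (n < 3) return(integer(0))
  cand <- which(y[2:(n - 1)] > y[1:(n - 2)] & y[2:(n - 1)] >= y[3:n]) + 1L
  if (length(cand) == 0) return(integer(0))
  prom <- vapply(cand, function(i) {
    hl <- which(y[seq_len(i - 1)] > y[i])
    lo_l <- min(y[(if (length(hl)) max(hl) else 1):i])
    hr <- which(y[(i + 1):n] > y[i])
    lo_r <- min(y[i:(if (length(hr)) i + min(hr) else n)])
    y[i] - max(lo_l, lo_r)
  }, numeric(1))
  keep <- cand[prom >= min_prominence]
  if (length(keep) <= 1 || min_separation_idx <= 1) return(sort(keep))
  ord <- keep[order(y[keep], decreasing = TRUE)]
  sel <- integer(0)
  for (i in ord)
    if (all(abs(i - sel) >= min_separation_idx)) sel <- c(sel, i)
  sort(sel)
}

# boxcar smoothing with edge replication; k forced odd
smooth_box <- function(y, k) {
  k <- as.integer(k)
  if (k <= 1) return(y)
  if (k %% 2 == 0) k <- k + 1L
  half <- k %/% 2
  yp <- c(rep(y[1], half), y, rep(y[length(y)], half))
  as.numeric(stats::filter(yp, rep(1 / k, k), sides = 2))[(half + 1):(half + length(y))]
}

#' Collagen D-period measurement from a line profile
#'
#' Detects crest maxima along a fibril profile and measures each D-unit as
#' the distance between the maximum heights of two adjoining crests. The
#' profile is first boxcar-smoothed over ~`smooth_nm` (short against any
#' plausible D-period, so crest positions are preserved while
#' single-sample noise spikes are suppressed); crests are local maxima of
#' the smoothed profile with topographic prominence at least
#' `min_prominence_nm`, thinned to a minimum mutual separation of
#' `min_separation_nm`, and localized to sub-sample precision by a
#' three-point parabolic fit around each crest sample. Defaults:
#' prominence 10% of the smoothed profile's peak-to-peak range and 30 nm
#' separation — below any plausible D-period, above the noise scale.
#'
#' @param p a `line_profile` from [extract_profile()]
#' @param min_prominence_nm minimum crest prominence in nm (default 10% of
#'   the smoothed peak-to-peak range)
#' @param min_separation_nm minimum crest separation in nm
#' @param smooth_nm boxcar pre-smoothing length in nm (0 disables)
#' @return a `d_period_result`: `crest_positions_nm`, `unit_lengths_nm`
#'   (adjacent crest distances, one fewer than crests) and `mean_d_nm`
#' @export
d_periods <- function(p, min_prominence_nm = NULL, min_separation_nm = 30,
                      smooth_nm = 10) {
  spacing <- if (length(p$positions) > 1) p$positions[2] - p$positions[1] else 1
  ys <- smooth_box(p$heights, round(smooth_nm / spacing))
  if (is.null(min_prominence_nm))
    min_prominence_nm <- 0.1 * diff(range(ys))
  idx <- find_crests(ys, min_prominence_nm,
                     max(1L, ceiling(min_separation_nm / spacing)))
  if (length(idx) < 2)
    stop("fewer than two crests detected: D-period undefined")
  crest <- vapply(idx, function(i) {
    if (i <= 1 || i >= length(ys)) return(p$positions[i])
    denom <- ys[i - 1] - 2 * ys[i] + ys[i + 1]
    delta <- if (denom < 0) 0.5 * (ys[i - 1] - ys[i + 1]) / denom else 0
    p$positions[i] + max(-1, min(1, delta)) * spacing
  }, numeric(1))
  units <- diff(crest)
  structure(list(crest_positions_nm = crest, unit_lengths_nm = units,
                 mean_d_nm = mean(units)),
            class = "d_period_result")
}

#' Pooled mean D-period over several profiles
#'
#' @param results list of `d_period_result` objects (e.g. six profiles
#'   drawn along fibers of one scan)
#' @return mean of all unit lengths pooled across profiles, nm
#' @export
mean_d_period <- function(results) {
  if (length(results) < 1) stop("need at least one profile result")
  mean(unlist(lapply(results, `[[`, "unit_lengths_nm")))
}
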