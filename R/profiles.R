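#' Endpoints of along-fiber line profiles
#'
#' Builds `n` parallel line segments running along the fiber axis
#' (direction `angle_deg` from the x axis; taken from the topography's
#' generator metadata when omitted), spread evenly across the scan and
#' clipped to an inner margin box. Used to draw the six along-fiber lines
#' of a D-period measurement.
#'
#' @param t a [topography()]
#' @param n number of profiles (default 6)
#' @param angle_deg fiber direction in degrees; defaults to
#'   `t$meta$config$fiber_angle_deg`
#' @param margin_frac inner margin kept clear of the image edge, as a
#'   fraction of the scan size
#' @return list of 2 x 2 endpoint matrices (rows = `(x, y)` vertices, nm),
#'   suitable for [extract_profile()]
#' @export
fiber_profile_endpoints <- function(t, n = 6, angle_deg = NULL,
                                    margin_frac = 0.05) {
  if (is.null(angle_deg)) {
    angle_deg <- t$meta$config$fiber_angle_deg
    if (is.null(angle_deg))
      stop("angle_deg not given and not present in topography metadata")
  }
  lx <- (ncol(t$heights) - 1) * t$pixel_nm
  ly <- (nrow(t$heights) - 1) * t$pixel_nm
  m <- margin_frac * min(lx, ly)
  lo <- c(m, m); hi <- c(lx - m, ly - m)
  th <- angle_deg * pi / 180
  d <- c(cos(th), sin(th))        # along-fiber direction
  pp <- c(-sin(th), cos(th))      # perpendicular
  ctr <- c(lx, ly) / 2
  span <- 0.35 * min(lx, ly)
  offsets <- if (n == 1) 0 else seq(-span, span, length.out = n)
  out <- list()
  for (o in offsets) {
    p0 <- ctr + o * pp
    # clip the infinite line p0 + t*d to the margin box
    t_lo <- -Inf; t_hi <- Inf
    for (k in 1:2) {
      if (abs(d[k]) < 1e-12) {
        if (p0[k] < lo[k] || p0[k] > hi[k]) { t_lo <- Inf; break }
      } else {
        t1 <- (lo[k] - p0[k]) / d[k]; t2 <- (hi[k] - p0[k]) / d[k]
        t_lo <- max(t_lo, min(t1, t2)); t_hi <- min(t_hi, max(t1, t2))
      }
    }
    if (!is.finite(t_lo) || t_hi - t_lo < 0.2 * min(lx, ly)) next
    out[[length(out) + 1L]] <- rbind(p0 + t_lo * d, p0 + t_hi * d)
  }
  if (length(out) < n)
    warning(sprintf("only %d of %d profiles fit inside the scan", length(out), n))
  out
}
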