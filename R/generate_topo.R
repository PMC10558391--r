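#' AFM topography container
#'
#' @param heights numeric matrix of surface heights in nm (rows = scan lines)
#' @param pixel_nm lateral pixel size in nm (square pixels); pixel centres
#'   sit at integer grid coordinates, physical position = index * pixel_nm
#' @param meta optional metadata list
#' @return a `topography` object
#' @export
topography <- function(heights, pixel_nm, meta = list()) {
  stopifnot(is.matrix(heights), is.numeric(heights), pixel_nm > 0)
  if (!all(is.finite(heights))) stop("heights must be finite")
  structure(list(heights = heights, pixel_nm = pixel_nm, meta = meta),
            class = "topography")
}

#' @export
print.topography <- function(x, ...) {
  cat(sprintf("<topography: %d x %d px, %.3f nm/px, range %.2f-%.2f nm>\n",
              nrow(x$heights), ncol(x$heights), x$pixel_nm,
              min(x$heights), max(x$heights)))
  invisible(x)
}

#' Synthetic collagen topography generator
#'
#' Emulates intermittent-contact AFM scans of aligned, D-banded collagen
#' fibrils: a raised-cosine height modulation of period `d_period_nm` along
#' the fiber axis (axial D-banding; raised cosine so crest maxima are
#' unambiguous and heights stay non-negative), superposed on a sample tilt
#' plane, per-scan-line height offsets (the slow-axis drift line flattening
#' removes), and Gaussian surface roughness.
#'
#' @param size_px image side length (default 512)
#' @param pixel_nm pixel size in nm (default 2500/512, a 2.5 um scan)
#' @param d_period_nm banding period along the fiber direction (default
#'   63.8 nm, a typical untreated collagen D-period); must exceed
#'   `2 * pixel_nm` (Nyquist)
#' @param band_amp_nm peak-to-trough banding amplitude in nm
#' @param background_rms_nm sd of the i.i.d. Gaussian roughness term
#' @param tilt_coeffs length-3 numeric `c(a, b, c)`: plane `a*x + b*y + c`
#'   with x = column index, y = row index (nm per pixel, nm)
#' @param line_offset_sd_nm sd of per-scan-line (row) height offsets
#' @param fiber_angle_deg fiber axis direction, degrees from the x axis
#' @param seed integer seed
#' @return `topo_gen_config()` returns a config list.
#' @export
topo_gen_config <- function(size_px = 512, pixel_nm = 2500 / 512,
                            d_period_nm = 63.8, band_amp_nm = 3,
                            background_rms_nm = 0.3,
                            tilt_coeffs = c(0.05, 0.05, 0),
                            line_offset_sd_nm = 2,
                            fiber_angle_deg = 30, seed = 1) {
  stopifnot(size_px >= 8, pixel_nm > 0, band_amp_nm >= 0,
            background_rms_nm >= 0, line_offset_sd_nm >= 0,
            length(tilt_coeffs) == 3)
  if (d_period_nm <= 2 * pixel_nm)
    stop("d_period_nm must exceed 2 * pixel_nm (Nyquist)")
  list(size_px = as.integer(size_px), pixel_nm = pixel_nm,
       d_period_nm = d_period_nm, band_amp_nm = band_amp_nm,
       background_rms_nm = background_rms_nm,
       tilt_coeffs = as.numeric(tilt_coeffs),
       line_offset_sd_nm = line_offset_sd_nm,
       fiber_angle_deg = fiber_angle_deg, seed = as.integer(seed))
}

#' @rdname topo_gen_config
#' @param cfg a [topo_gen_config()]
#' @return `generate_topography()` returns a [topography()]; `meta` records
#'   the config.
#' @export
generate_topography <- function(cfg) {
  if (cfg$d_period_nm <= 2 * cfg$pixel_nm)
    stop("d_period_nm must exceed 2 * pixel_nm (Nyquist)")
  n <- cfg$size_px
  xi <- matrix(rep(0:(n - 1), each = n), n, n)   # column index
  yi <- matrix(rep(0:(n - 1), times = n), n, n)  # row index
  th <- cfg$fiber_angle_deg * pi / 180
  u_nm <- (xi * cos(th) + yi * sin(th)) * cfg$pixel_nm
  h <- cfg$band_amp_nm / 2 * (1 + cos(2 * pi * u_nm / cfg$d_period_nm))
  tc <- cfg$tilt_coeffs
  h <- h + tc[1] * xi + tc[2] * yi + tc[3]
  set.seed(sub_seed(cfg$seed, 1))
  if (cfg$line_offset_sd_nm > 0)
    h <- h + stats::rnorm(n, 0, cfg$line_offset_sd_nm)  # recycled down rows
  if (cfg$background_rms_nm > 0)
    h <- h + matrix(stats::rnorm(n * n, 0, cfg$background_rms_nm), n, n)
  topography(h, cfg$pixel_nm, meta = list(config = cfg))
}
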