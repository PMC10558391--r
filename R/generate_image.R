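#' Two-channel multiphoton image container
#'
#' Paired TPEF (two-photon excited fluorescence) and SHG (second-harmonic
#' generation) intensity grids with a common pixel size.
#'
#' @param tpef,shg non-negative numeric matrices of equal shape, at least
#'   100 x 100 pixels
#' @param pixel_um pixel size in micrometres
#' @param meta optional metadata list (generator preset, seed, expected
#'   channel means)
#' @return a `multimodal_image` object
#' @export
multimodal_image <- function(tpef, shg, pixel_um, meta = list()) {
  stopifnot(is.matrix(tpef), is.matrix(shg), is.numeric(pixel_um),
            pixel_um > 0)
  if (!all(dim(tpef) == dim(shg))) stop("tpef and shg must have equal shape")
  if (any(dim(tpef) < 100)) stop("image must be at least 100 x 100 pixels")
  if (min(tpef) < 0 || min(shg) < 0) stop("intensities must be non-negative")
  structure(list(tpef = tpef, shg = shg, pixel_um = pixel_um, meta = meta),
            class = "multimodal_image")
}

#' @export
print.multimodal_image <- function(x, ...) {
  cat(sprintf("<multimodal_image: %d x %d px, %.3f um/px>\n",
              nrow(x$tpef), ncol(x$tpef), x$pixel_um))
  invisible(x)
}

#' Synthetic multiphoton image-pair generator
#'
#' Renders a collagen fiber field (wavy, sinusoidally perturbed ridges with
#' Gaussian cross-section — the morphology the SHG channel shows) and an
#' elastin fiber field (straight rectilinear ridges — the TPEF morphology),
#' then mixes them according to the glycation preset's fluorescence-transfer
#' fraction `g`: pentosidine crosslinks make collagen fluorescent while
#' degrading its SHG-generating order, so
#' \deqn{SHG = (1 - g) \cdot collagen + noise, \quad
#'       TPEF = elastin + g \cdot collagen + noise.}
#' With `calibrate = TRUE` (default) the elastin field is rescaled so both
#' fields have equal mean intensity, which makes the expected ratio of
#' channel means exactly `(1 + g) / 2` (see [expected_tpef_ratio()]).
#' Gaussian noise is added per channel and negative values are clamped to 0
#' (detector-like rectification); with `noise_sd = 0` the conservation
#' identity `TPEF + SHG = elastin + collagen` holds exactly.
#'
#' @param size_px image side length in pixels (>= 100, default 2048)
#' @param pixel_um pixel size (default 225 um / 2048 px)
#' @param n_collagen_fibers,n_elastin_fibers number of rendered fibers;
#'   defaults keep the centre-line spacing fixed in pixels (dense, aligned
#'   tissue) as `size_px` changes
#' @param collagen_amp,elastin_amp peak fiber intensities (arbitrary units)
#' @param waviness dimensionless collagen waviness; the sinusoidal
#'   centre-line amplitude is `waviness * 0.025 * size_px` pixels
#' @param noise_sd additive Gaussian noise sd, intensity units (default 5%
#'   of `collagen_amp`)
#' @param background_frac diffuse (unstructured matrix) signal added to
#'   each fiber field, as a fraction of that field's mean intensity
#' @param calibrate rescale the elastin field to the collagen field mean
#' @param seed integer seed
#' @return `image_gen_config()` returns a config list.
#' @export
image_gen_config <- function(size_px = 2048, pixel_um = 225 / 2048,
                             n_collagen_fibers = round(size_px / 7),
                             n_elastin_fibers = round(size_px / 10),
                             collagen_amp = 1000, elastin_amp = 1000,
                             waviness = 0.5, noise_sd = 0.05 * collagen_amp,
                             background_frac = 0.3,
                             calibrate = TRUE, seed = 1) {
  stopifnot(size_px >= 100, collagen_amp >= 0, elastin_amp >= 0,
            noise_sd >= 0, pixel_um > 0, waviness >= 0, background_frac >= 0)
  list(size_px = as.integer(size_px), pixel_um = pixel_um,
       n_collagen_fibers = n_collagen_fibers,
       n_elastin_fibers = n_elastin_fibers,
       collagen_amp = collagen_amp, elastin_amp = elastin_amp,
       waviness = waviness, noise_sd = noise_sd,
       background_frac = background_frac, calibrate = calibrate,
       seed = as.integer(seed))
}

# Render n mostly-horizontal ridges with Gaussian cross-section into an
# N x N field. Fibers sit on a jittered regular grid of centre lines
# (parallel, near-evenly spaced, as in aligned tissue), each with a random
# thickness and (optionally) a sinusoidal centre-line perturbation. Only
# the row window within 4 sigma of the centre line is touched, which keeps
# rendering fast at 2048^2.
render_fiber_field <- function(n_px, n_fibers, amp, wave_amp_px) {
  field <- matrix(0, n_px, n_px)
  x <- seq_len(n_px)
  spacing <- n_px / n_fibers
  for (i in seq_len(n_fibers)) {
    y0 <- (i - 0.5) * spacing + stats::runif(1, -0.3, 0.3) * spacing
    sg <- stats::runif(1, 0.0008 * n_px + 1.5, 0.0015 * n_px + 2.5)
    if (wave_amp_px > 0) {
      lam <- stats::runif(1, 0.08, 0.25) * n_px
      ph <- stats::runif(1, 0, 2 * pi)
      cx <- y0 + wave_amp_px * sin(2 * pi * x / lam + ph)
    } else {
      slope <- tan(stats::runif(1, -5, 5) * pi / 180)
      cx <- y0 + slope * (x - n_px / 2)
    }
    r0 <- max(1L, floor(min(cx) - 4 * sg))
    r1 <- min(n_px, ceiling(max(cx) + 4 * sg))
    if (r0 > r1) next
    rows <- r0:r1
    field[rows, ] <- field[rows, ] +
      amp * exp(-outer(rows, cx, `-`)^2 / (2 * sg^2))
  }
  field
}

#' @rdname image_gen_config
#' @param cfg an [image_gen_config()]
#' @param preset a [glycation_preset()]; only its `fluor_transfer_g` is used
#' @return `generate_image_pair()` returns a [multimodal_image()] whose
#'   `meta` records the preset, seed, transfer fraction `g`, the rendered
#'   field means (`elastin_mean`, `collagen_mean`) and the closed-form
#'   `expected_tpef_ratio`.
#' @export
generate_image_pair <- function(cfg, preset) {
  g <- preset$fluor_transfer_g
  stopifnot(g >= 0, g <= 1)
  n <- cfg$size_px
  set.seed(sub_seed(cfg$seed, 1))
  collagen <- render_fiber_field(n, cfg$n_collagen_fibers, cfg$collagen_amp,
                                 wave_amp_px = cfg$waviness * 0.025 * n)
  set.seed(sub_seed(cfg$seed, 2))
  elastin <- render_fiber_field(n, cfg$n_elastin_fibers, cfg$elastin_amp,
                                wave_amp_px = 0)
  if (cfg$background_frac > 0) {
    collagen <- collagen + cfg$background_frac * mean(collagen)
    elastin <- elastin + cfg$background_frac * mean(elastin)
  }
  if (isTRUE(cfg$calibrate) && mean(elastin) > 0)
    elastin <- elastin * (mean(collagen) / mean(elastin))
  shg <- (1 - g) * collagen
  tpef <- elastin + g * collagen
  if (cfg$noise_sd > 0) {
    set.seed(sub_seed(cfg$seed, 3))
    tpef <- pmax(tpef + matrix(stats::rnorm(n * n, 0, cfg$noise_sd), n, n), 0)
    shg <- pmax(shg + matrix(stats::rnorm(n * n, 0, cfg$noise_sd), n, n), 0)
  }
  multimodal_image(tpef, shg, cfg$pixel_um, meta = list(
    preset = preset, seed = cfg$seed, g = g,
    elastin_mean = mean(elastin), collagen_mean = mean(collagen),
    expected_tpef_ratio = expected_tpef_ratio(g, mean(elastin), mean(collagen))))
}
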