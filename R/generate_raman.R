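#' Synthetic Raman dataset generator
#'
#' Emulates grid-scan Raman measurements of untreated and ribose-glycated
#' collagenous tissue. Each spectrum is a sum of Lorentzian collagen bands
#' ([make_collagen_bands()]) perturbed by the preset's glycation effect
#' ([apply_glycation()]), plus a random linear baseline and i.i.d. Gaussian
#' shot-like noise. Sample-to-sample glycation heterogeneity is emulated by
#' jittering the effect scale per spectrum (additive Gaussian,
#' `effect_jitter_sd`, clamped to [0, 1]); untreated spectra
#' (`effect_scale = 0`) are never jittered, so the 0 mM class stays exactly
#' at zero effect.
#'
#' @param axis_lo,axis_hi,axis_step wavenumber axis in cm^-1 (default
#'   600-1800 cm^-1 in 2 cm^-1 steps, wider than the 800-1750 fingerprint
#'   region so that cropping is a real operation)
#' @param baseline_slope_sd sd of the random linear baseline slope,
#'   intensity units per cm^-1
#' @param baseline_offset_sd sd of the random baseline offset, intensity units
#' @param noise_sd Gaussian noise sd as a fraction of the maximum band
#'   amplitude of the unperturbed model
#' @param effect_jitter_sd sd of the per-spectrum additive jitter on
#'   `effect_scale` (glycation heterogeneity across the sampled grid)
#' @param seed integer seed; equal seeds give bit-identical datasets
#' @return `raman_gen_config()` returns a config list.
#' @export
raman_gen_config <- function(axis_lo = 600, axis_hi = 1800, axis_step = 2,
                             baseline_slope_sd = 2e-4,
                             baseline_offset_sd = 0.05,
                             noise_sd = 0.01,
                             effect_jitter_sd = 0.05,
                             seed = 1) {
  stopifnot(axis_lo < axis_hi, axis_step > 0, noise_sd >= 0,
            baseline_slope_sd >= 0, baseline_offset_sd >= 0,
            effect_jitter_sd >= 0)
  list(axis_lo = axis_lo, axis_hi = axis_hi, axis_step = axis_step,
       baseline_slope_sd = baseline_slope_sd,
       baseline_offset_sd = baseline_offset_sd,
       noise_sd = noise_sd, effect_jitter_sd = effect_jitter_sd,
       seed = as.integer(seed))
}

raman_axis <- function(cfg) seq(cfg$axis_lo, cfg$axis_hi, by = cfg$axis_step)

#' Noiseless untreated collagen spectrum
#'
#' The pure-component spectrum of the generator: the unperturbed band model
#' evaluated on the config axis with no baseline and no noise. It serves as
#' the reference ("pure component") for EMSC correction.
#'
#' @param cfg a [raman_gen_config()]
#' @return a [spectrum()]
#' @export
collagen_reference_spectrum <- function(cfg = raman_gen_config()) {
  w <- raman_axis(cfg)
  spectrum(w, lorentzian_sum(w, make_collagen_bands()))
}

#' @rdname raman_gen_config
#' @param cfg a [raman_gen_config()]
#' @param presets list of [glycation_preset()] objects, one class each
#' @param n_per_class number of spectra per preset (>= 1)
#' @return `generate_raman_dataset()` returns a [spectral_dataset()] with
#'   labels `spectrum_id`, `concentration_mM`, `day`, `sample_id`,
#'   `grid_position` and `effect_scale_used`.
#' @export
generate_raman_dataset <- function(cfg, presets, n_per_class) {
  if (length(presets) == 0) stop("presets must be a non-empty list")
  if (inherits(presets, "glycation_preset")) presets <- list(presets)
  stopifnot(n_per_class >= 1)
  w <- raman_axis(cfg)
  base_bands <- make_collagen_bands()
  max_amp <- max(vapply(base_bands, `[[`, numeric(1), "amplitude"))
  cols <- list(); labs <- list()
  for (j in seq_along(presets)) {
    p <- presets[[j]]
    set.seed(sub_seed(cfg$seed, j))
    for (i in seq_len(n_per_class)) {
      s <- p$effect_scale
      if (s > 0 && cfg$effect_jitter_sd > 0)
        s <- min(1, max(0, s + stats::rnorm(1, 0, cfg$effect_jitter_sd)))
      bands <- apply_glycation(base_bands, s)
      y <- lorentzian_sum(w, bands)
      slope <- stats::rnorm(1, 0, cfg$baseline_slope_sd)
      offset <- stats::rnorm(1, 0, cfg$baseline_offset_sd)
      y <- y + offset + slope * (w - cfg$axis_lo)
      if (cfg$noise_sd > 0)
        y <- y + stats::rnorm(length(w), 0, cfg$noise_sd * max_amp)
      cols[[length(cols) + 1L]] <- y
      labs[[length(labs) + 1L]] <- data.frame(
        concentration_mM = p$concentration_mM, day = p$day,
        sample_id = j, grid_position = i, effect_scale_used = s)
    }
  }
  labels <- do.call(rbind, labs)
  labels$spectrum_id <- sprintf("s%04d", seq_len(nrow(labels)))
  spectral_dataset(w, do.call(cbind, cols), labels)
}
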