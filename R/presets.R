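#' Glycation presets: ribose concentration and incubation time to effect sizes
#'
#' A preset ties one experimental condition (ribose concentration in mM and
#' incubation day) to the three generator effect sizes: `effect_scale`
#' (Raman band perturbation, [apply_glycation()]), `fluor_transfer_g` (the
#' fraction of collagen signal appearing in the TPEF channel of generated
#' image pairs) and `roughness_rms_nm` (AFM surface roughness).
#'
#' The concentration/day mapping is saturating in concentration and linear
#' in time: `severity(c, day) = log(1 + c/5) / log(1 + 200/5) * day / 30`,
#' which is 0 for untreated tissue and 1 at 200 mM after 30 days. Effect
#' sizes scale linearly with severity; `fluor_transfer_g` reaches
#' `g_max = 0.26` (the value whose calibrated-channel expected TPEF ratio is
#' 0.63, see [g_for_ratio()]) and `roughness_rms_nm` interpolates from
#' 11.64 nm (untreated) to 21.78 nm (fully glycated).
#'
#' @param concentration_mM ribose concentration, one of 0, 5, 50, 100, 200
#' @param day incubation day, one of 10, 20, 30
#' @param effect_scale,fluor_transfer_g,roughness_rms_nm optional overrides
#'   of the derived defaults
#' @return a `glycation_preset` object (named list)
#' @examples
#' glycation_preset(200, 30)       # fully glycated
#' glycation_preset(0, 30)         # untreated: all optical effects zero
#' @export
glycation_preset <- function(concentration_mM, day,
                             effect_scale = NULL,
                             fluor_transfer_g = NULL,
                             roughness_rms_nm = NULL) {
  if (!concentration_mM %in% c(0, 5, 50, 100, 200))
    stop("concentration_mM must be one of 0, 5, 50, 100, 200")
  if (!day %in% c(10, 20, 30))
    stop("day must be one of 10, 20, 30")
  sev <- glycation_severity(concentration_mM, day)
  if (is.null(effect_scale)) effect_scale <- sev
  if (is.null(fluor_transfer_g)) fluor_transfer_g <- 0.26 * sev
  if (is.null(roughness_rms_nm))
    roughness_rms_nm <- 11.64 + (21.78 - 11.64) * sev
  stopifnot(effect_scale >= 0, effect_scale <= 1,
            fluor_transfer_g >= 0, fluor_transfer_g <= 1,
            roughness_rms_nm >= 0)
  if (concentration_mM == 0 && (effect_scale != 0 || fluor_transfer_g != 0))
    stop("untreated preset (0 mM) must have zero effect_scale and fluor_transfer_g")
  structure(list(concentration_mM = concentration_mM, day = day,
                 effect_scale = effect_scale,
                 fluor_transfer_g = fluor_transfer_g,
                 roughness_rms_nm = roughness_rms_nm),
            class = "glycation_preset")
}

#' @rdname glycation_preset
#' @export
glycation_severity <- function(concentration_mM, day) {
  log1p(concentration_mM / 5) / log1p(200 / 5) * day / 30
}

#' @rdname glycation_preset
#' @param days,concentrations_mM grids over which to build the preset table
#' @return `preset_table()` returns a list of presets, ordered by day then
#'   concentration.
#' @export
preset_table <- function(days = c(10, 20, 30),
                         concentrations_mM = c(0, 5, 50, 100, 200)) {
  out <- list()
  for (d in days) for (cc in concentrations_mM)
    out[[length(out) + 1L]] <- glycation_preset(cc, d)
  out
}

#' @export
print.glycation_preset <- function(x, ...) {
  cat(sprintf("<preset %g mM, day %g: effect %.3f, g %.3f, roughness %.2f nm>\n",
              x$concentration_mM, x$day, x$effect_scale, x$fluor_transfer_g,
              x$roughness_rms_nm))
  invisible(x)
}

#' Closed-form expected TPEF ratio of generated image pairs, and its inverse
#'
#' With fluorescence transfer `g`, the generator's noiseless channels are
#' `TPEF = E + g C` and `SHG = (1 - g) C`, where `E` and `C` are the mean
#' elastin and collagen field intensities, so the expected ratio of channel
#' means is `(E + g C) / (E + C)`. With calibrated channels (`E = C`, the
#' generator default) this reduces to `(1 + g) / 2`, whose inverse is
#' `g = 2 r - 1`.
#'
#' @param g fluorescence transfer fraction in [0, 1]
#' @param elastin_mean,collagen_mean mean field intensities (equal by default)
#' @return `expected_tpef_ratio()`: the expected ratio in [0, 1].
#' @export
expected_tpef_ratio <- function(g, elastin_mean = 1, collagen_mean = 1) {
  stopifnot(g >= 0, g <= 1, elastin_mean >= 0, collagen_mean >= 0)
  (elastin_mean + g * collagen_mean) / (elastin_mean + collagen_mean)
}

#' @rdname expected_tpef_ratio
#' @param ratio target expected TPEF ratio, in [0.5, 1] for calibrated channels
#' @return `g_for_ratio()`: the transfer fraction g with that expected ratio.
#' @export
g_for_ratio <- function(ratio) {
  stopifnot(ratio >= 0.5, ratio <= 1)
  2 * ratio - 1
}
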