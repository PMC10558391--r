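#' Collagen Raman band model
#'
#' A band is a Lorentzian line with a centre (cm^-1), a full width at half
#' maximum (cm^-1) and a peak amplitude (arbitrary intensity units).
#' [make_collagen_bands()] returns the default eleven-band model of a
#' collagen/elastin fingerprint spectrum; [apply_glycation()] perturbs it the
#' way ribose glycation perturbs real spectra.
#'
#' @param center band centre in cm^-1, within the 800-1750 fingerprint region
#' @param width full width at half maximum in cm^-1, > 0
#' @param amplitude peak height in arbitrary units, >= 0
#' @return `band_spec()` returns a `band_spec` object (a named list).
#' @export
band_spec <- function(center, width, amplitude) {
  stopifnot(is.numeric(center), length(center) == 1L,
            is.numeric(width), length(width) == 1L,
            is.numeric(amplitude), length(amplitude) == 1L)
  if (center < 800 || center > 1750)
    stop("band centre must lie in the fingerprint region [800, 1750] cm^-1")
  if (width <= 0) stop("band width (FWHM) must be > 0")
  if (amplitude < 0) stop("band amplitude must be >= 0")
  structure(list(center = center, width = width, amplitude = amplitude),
            class = "band_spec")
}

#' @export
print.band_spec <- function(x, ...) {
  cat(sprintf("<band %g cm-1, FWHM %g cm-1, amplitude %g>\n",
              x$center, x$width, x$amplitude))
  invisible(x)
}

#' Default collagen/elastin band table
#'
#' Eleven Lorentzian bands of a pericardial collagen/elastin fingerprint
#' spectrum: 816 (proline), 856 and 873 (hydroxyproline), 922 and 938
#' (C-C-alpha stretch), 1002 (phenylalanine), 1244 and 1272 (amide III),
#' 1451 (CH2/CH3 deformation, the normalization anchor), 1640 (water) and
#' 1666 cm^-1 (amide I). Widths default to 12 cm^-1 FWHM except the sharp
#' phenylalanine ring mode (8 cm^-1) and the broad water band (25 cm^-1);
#' amplitudes are relative units chosen so the band-height ordering is that
#' of a typical collagen spectrum, with the 1451 anchor strongest.
#'
#' @return list of [band_spec()] objects, one per band.
#' @examples
#' bands <- make_collagen_bands()
#' vapply(bands, `[[`, numeric(1), "center")
#' @export
make_collagen_bands <- function() {
  tab <- collagen_band_table()
  Map(band_spec, tab$center, tab$width, tab$amplitude)
}

#' @rdname make_collagen_bands
#' @return `collagen_band_table()` returns the same model as a data.frame
#'   with columns `center`, `width`, `amplitude` (so tests and documentation
#'   can read the defaults in one place).
#' @export
collagen_band_table <- function() {
  data.frame(
    center    = c(816, 856, 873, 922, 938, 1002, 1244, 1272, 1451, 1640, 1666),
    width     = c(12, 12, 12, 12, 12, 8, 12, 12, 12, 25, 12),
    amplitude = c(0.30, 0.45, 0.40, 0.35, 0.40, 0.50, 0.55, 0.55, 1.00, 0.35, 0.90)
  )
}

#' Glycation effect table
#'
#' Linear band-amplitude effects applied by [apply_glycation()] at full
#' effect (`effect_scale = 1`). Positive discriminant bands (938 and the
#' 1634/1643 region, represented by the 1640 band of the base model) gain
#' intensity, negative ones (922, the amide-III flank at 1272 standing for
#' the 1298 region, and amide I at 1666 standing for 1660) lose intensity,
#' each multiplicatively; a new broad band appears at 1372 cm^-1 (FWHM
#' 30 cm^-1) with amplitude `0.25 * effect_scale`. The 1451 anchor is never
#' touched so normalization stays well defined.
#'
#' @return data.frame with columns `center` and `rel_change` (fractional
#'   amplitude change at `effect_scale = 1`).
#' @export
glycation_effect_table <- function() {
  data.frame(
    center     = c(938, 1640, 922, 1272, 1666),
    rel_change = c(+0.50, +0.40, -0.45, -0.25, -0.30)
  )
}

#' Amplitude of the glycation marker band at 1372 cm^-1 for a given effect
#' scale (linear: `0.25 * effect_scale`); its FWHM is fixed at 30 cm^-1.
#' @param effect_scale dimensionless glycation effect in [0, 1]
#' @keywords internal
glycation_band_1372 <- function(effect_scale) {
  list(center = 1372, width = 30, amplitude = 0.25 * effect_scale)
}

#' Apply a glycation perturbation to a band model
#'
#' Scales the amplitudes listed in [glycation_effect_table()] by
#' `1 + rel_change * effect_scale` and, for `effect_scale > 0`, appends the
#' broad 1372 cm^-1 marker band. All effects are linear in `effect_scale`;
#' the 1451 cm^-1 anchor band is left unchanged.
#'
#' @param bands list of [band_spec()] objects
#' @param effect_scale dimensionless effect in [0, 1]; 0 returns the input
#'   unchanged
#' @return list of `band_spec` objects
#' @export
apply_glycation <- function(bands, effect_scale) {
  stopifnot(is.numeric(effect_scale), length(effect_scale) == 1L)
  if (is.na(effect_scale) || effect_scale < 0 || effect_scale > 1)
    stop("effect_scale must lie in [0, 1]")
  if (effect_scale == 0) return(bands)
  eff <- glycation_effect_table()
  out <- lapply(bands, function(b) {
    i <- match(b$center, eff$center)
    if (is.na(i)) return(b)
    band_spec(b$center, b$width,
              b$amplitude * (1 + eff$rel_change[i] * effect_scale))
  })
  g <- glycation_band_1372(effect_scale)
  c(out, list(band_spec(g$center, g$width, g$amplitude)))
}

#' Evaluate a sum of Lorentzian bands on a wavenumber axis
#'
#' Each band contributes `amplitude * (w/2)^2 / ((x - center)^2 + (w/2)^2)`,
#' i.e. a Lorentzian with peak height `amplitude` and FWHM `width`.
#'
#' @param wavenumbers numeric axis in cm^-1
#' @param bands list of [band_spec()] objects
#' @return numeric vector of intensities, same length as `wavenumbers`
#' @export
lorentzian_sum <- function(wavenumbers, bands) {
  y <- numeric(length(wavenumbers))
  for (b in bands) {
    hw2 <- (b$width / 2)^2
    y <- y + b$amplitude * hw2 / ((wavenumbers - b$center)^2 + hw2)
  }
  y
}
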