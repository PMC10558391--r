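#' Crop a spectrum to the fingerprint region
#'
#' Keeps the points with `lo <= wavenumber <= hi` (closed interval), order
#' preserved. The 800-1750 cm^-1 default covers the biomolecular
#' fingerprint bands used throughout the analysis.
#'
#' @param s a [spectrum()]
#' @param lo,hi region bounds in cm^-1
#' @return a [spectrum()] restricted to the region
#' @export
crop_fingerprint <- function(s, lo = 800, hi = 1750) {
  keep <- s$wavenumbers >= lo & s$wavenumbers <= hi
  if (!any(keep))
    stop(sprintf("spectrum axis (%g-%g) does not overlap [%g, %g]",
                 min(s$wavenumbers), max(s$wavenumbers), lo, hi))
  spectrum(s$wavenumbers[keep], s$intensities[keep])
}

#' Background design for extended multiplicative signal correction
#'
#' Builds the background component matrix of the EMSC model. The default
#' (`type = "hats"`) is a linear-spline ("hat") basis: five piecewise-linear
#' functions on an equal four-interval partition of the axis, each peaking
#' at one knot and scaled to unit maximum. Their span contains every global
#' linear baseline (constant + slope) plus slowly varying piecewise-linear
#' backgrounds. `type = "poly"` gives monomials of degree 0 to
#' `n_background - 1` on the axis rescaled to [-1, 1], each scaled to unit
#' maximum absolute value.
#'
#' @param reference a [spectrum()] defining the working axis
#' @param n_background number of background components (>= 1; the model
#'   default is five)
#' @param type `"hats"` (linear spline) or `"poly"` (monomials)
#' @return numeric matrix, one column per background component, with
#'   attribute `"type"`
#' @export
build_emsc_basis <- function(reference, n_background = 5,
                             type = c("hats", "poly")) {
  type <- match.arg(type)
  if (n_background < 1) stop("n_background must be >= 1")
  w <- reference$wavenumbers
  if (n_background == 1) {
    B <- matrix(1, length(w), 1)
  } else if (type == "hats") {
    knots <- seq(min(w), max(w), length.out = n_background)
    B <- vapply(seq_len(n_background), function(i) {
      left <- if (i == 1) knots[1] else knots[i - 1]
      right <- if (i == n_background) knots[n_background] else knots[i + 1]
      up <- if (knots[i] > left) pmax(0, (w - left) / (knots[i] - left)) else as.numeric(w >= knots[i])
      dn <- if (right > knots[i]) pmax(0, (right - w) / (right - knots[i])) else as.numeric(w <= knots[i])
      hat <- pmin(up, dn)
      hat / max(hat)  # knots may fall off-grid; rescale to unit maximum
    }, numeric(length(w)))
  } else {
    z <- 2 * (w - min(w)) / (max(w) - min(w)) - 1
    B <- vapply(seq_len(n_background), function(i) {
      col <- z^(i - 1)
      col / max(abs(col))
    }, numeric(length(w)))
  }
  attr(B, "type") <- type
  B
}

#' EMSC baseline correction against a reference spectrum
#'
#' Extended multiplicative signal correction: the spectrum is modelled by
#' ordinary least squares as
#' \deqn{s \approx b \cdot reference + \sum_i a_i \cdot basis_i,}
#' where the reference is a pure-component spectrum (untreated tissue) and
#' the basis columns span slowly varying backgrounds. The corrected
#' spectrum removes the fitted background and the multiplicative scale:
#' `corrected = (s - sum_i a_i basis_i) / b = reference + e / b`, so the
#' chemical residual `e` is preserved (rescaled), not discarded.
#'
#' @param s spectrum to correct
#' @param reference pure-component [spectrum()] on the same axis
#' @param basis background matrix from [build_emsc_basis()]
#' @return an `emsc_fit`: list with `b` (multiplicative coefficient), `a`
#'   (background coefficients), `corrected` ([spectrum()]) and
#'   `residual_norm` (Euclidean norm of the LS residual)
#' @export
emsc_correct <- function(s, reference, basis) {
  if (length(s$wavenumbers) != length(reference$wavenumbers) ||
      any(s$wavenumbers != reference$wavenumbers))
    stop("spectrum and reference must share one wavenumber axis")
  if (nrow(basis) != length(s$wavenumbers))
    stop("basis must be built on the shared axis")
  D <- cbind(reference$intensities, basis)
  coef <- qr.coef(qr(D), s$intensities)
  if (anyNA(coef)) stop("EMSC design is rank deficient")
  b <- coef[1]
  a <- coef[-1]
  if (abs(b) < 1e-8)
    stop("degenerate EMSC fit: multiplicative coefficient ~ 0")
  background <- as.numeric(basis %*% a)
  corrected <- (s$intensities - background) / b
  resid <- s$intensities - as.numeric(D %*% coef)
  structure(list(b = unname(b), a = unname(a),
                 corrected = spectrum(s$wavenumbers, corrected),
                 residual_norm = sqrt(sum(resid^2))),
            class = "emsc_fit")
}

#' Normalize a spectrum at an anchor band
#'
#' Divides all intensities by the maximum intensity within
#' `center +/- half_window` cm^-1. The default anchor, 1451 cm^-1, is the
#' CH2/CH3 deformation band of collagen and elastin, which is insensitive
#' to glycation. Using the window maximum (rather than a single-point
#' lookup) makes the anchor robust to axis discretization.
#'
#' @param s a [spectrum()]
#' @param center anchor band centre, cm^-1
#' @param half_window half width of the anchor window, cm^-1
#' @return normalized [spectrum()]; its maximum within the window is 1
#' @export
normalize_at <- function(s, center = 1451, half_window = 5) {
  idx <- which(s$wavenumbers >= center - half_window &
               s$wavenumbers <= center + half_window)
  if (length(idx) == 0)
    stop(sprintf("axis does not cover the anchor window %g +/- %g cm^-1",
                 center, half_window))
  anchor <- max(s$intensities[idx])
  if (anchor <= 0)
    stop("non-positive anchor intensity: normalization undefined")
  spectrum(s$wavenumbers, s$intensities / anchor)
}

#' Preprocess a spectral dataset: crop, EMSC, normalize
#'
#' Applies [crop_fingerprint()], [emsc_correct()] against the (cropped)
#' reference, and [normalize_at()] to every spectrum, preserving labels.
#' If the reference axis differs from the dataset axis, the reference is
#' linearly interpolated onto the dataset's cropped axis.
#'
#' @param ds a [spectral_dataset()]
#' @param reference untreated pure-component [spectrum()]
#' @param lo,hi crop bounds (cm^-1)
#' @param anchor,half_window normalization anchor (cm^-1)
#' @param n_background,basis_type EMSC background design, see
#'   [build_emsc_basis()]
#' @return preprocessed [spectral_dataset()]; attribute `"preproc_log"`
#'   holds a data.frame of per-spectrum EMSC `b` and `residual_norm`
#' @export
preprocess_dataset <- function(ds, reference, lo = 800, hi = 1750,
                               anchor = 1451, half_window = 5,
                               n_background = 5, basis_type = "hats") {
  keep <- ds$wavenumbers >= lo & ds$wavenumbers <= hi
  if (!any(keep)) stop("dataset axis does not overlap the crop region")
  w <- ds$wavenumbers[keep]
  ref <- if (length(reference$wavenumbers) == length(w) &&
             all(reference$wavenumbers == w)) {
    reference
  } else {
    spectrum(w, stats::approx(reference$wavenumbers, reference$intensities,
                              xout = w, rule = 1)$y)
  }
  basis <- build_emsc_basis(ref, n_background, basis_type)
  out <- matrix(NA_real_, length(w), n_spectra(ds))
  log <- data.frame(spectrum_id = ds$labels$spectrum_id,
                    b = NA_real_, residual_norm = NA_real_)
  for (i in seq_len(n_spectra(ds))) {
    s <- spectrum(w, ds$intensities[keep, i])
    fit <- tryCatch({
      f <- emsc_correct(s, ref, basis)
      list(spec = normalize_at(f$corrected, anchor, half_window),
           b = f$b, rn = f$residual_norm)
    }, error = function(e) {
      stop(sprintf("spectrum '%s': %s", ds$labels$spectrum_id[i],
                   conditionMessage(e)), call. = FALSE)
    })
    out[, i] <- fit$spec$intensities
    log$b[i] <- fit$b
    log$residual_norm[i] <- fit$rn
  }
  res <- spectral_dataset(w, out, ds$labels)
  attr(res, "preproc_log") <- log
  attr(res, "basis_type") <- basis_type
  res
}
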