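#' Raman spectrum and spectral dataset containers
#'
#' A `spectrum` is a strictly increasing wavenumber axis (cm^-1) with one
#' intensity vector; a `spectral_dataset` holds many spectra on one shared
#' axis (intensities as a wavenumber-by-spectrum matrix) plus a per-spectrum
#' label table.
#'
#' @param wavenumbers numeric, strictly increasing, no missing values
#' @param intensities numeric, same length as `wavenumbers`
#' @return a `spectrum` object
#' @export
spectrum <- function(wavenumbers, intensities) {
  stopifnot(is.numeric(wavenumbers), is.numeric(intensities))
  if (length(wavenumbers) != length(intensities))
    stop("wavenumbers and intensities must have equal length")
  if (anyNA(wavenumbers) || anyNA(intensities))
    stop("spectrum must not contain missing values")
  if (length(wavenumbers) > 1 && any(diff(wavenumbers) <= 0))
    stop("wavenumbers must be strictly increasing")
  structure(list(wavenumbers = as.numeric(wavenumbers),
                 intensities = as.numeric(intensities)),
            class = "spectrum")
}

#' @export
print.spectrum <- function(x, ...) {
  cat(sprintf("<spectrum: %d points, %g-%g cm-1>\n", length(x$wavenumbers),
              min(x$wavenumbers), max(x$wavenumbers)))
  invisible(x)
}

#' @rdname spectrum
#' @param intensity_matrix numeric matrix, rows = wavenumbers, columns = spectra
#' @param labels data.frame with one row per spectrum; a `spectrum_id` column
#'   is added if absent
#' @return a `spectral_dataset` object
#' @export
spectral_dataset <- function(wavenumbers, intensity_matrix, labels) {
  intensity_matrix <- as.matrix(intensity_matrix)
  stopifnot(is.numeric(wavenumbers), is.numeric(intensity_matrix),
            is.data.frame(labels))
  if (nrow(intensity_matrix) != length(wavenumbers))
    stop("intensity matrix must have one row per wavenumber")
  if (ncol(intensity_matrix) != nrow(labels))
    stop("labels must have one row per spectrum")
  if (anyNA(intensity_matrix)) stop("dataset must not contain missing values")
  if (length(wavenumbers) > 1 && any(diff(wavenumbers) <= 0))
    stop("wavenumbers must be strictly increasing")
  if (is.null(labels$spectrum_id))
    labels$spectrum_id <- sprintf("s%04d", seq_len(nrow(labels)))
  colnames(intensity_matrix) <- labels$spectrum_id
  structure(list(wavenumbers = as.numeric(wavenumbers),
                 intensities = intensity_matrix,
                 labels = labels),
            class = "spectral_dataset")
}

#' @export
print.spectral_dataset <- function(x, ...) {
  cat(sprintf("<spectral_dataset: %d spectra x %d points, %g-%g cm-1>\n",
              n_spectra(x), length(x$wavenumbers),
              min(x$wavenumbers), max(x$wavenumbers)))
  invisible(x)
}

#' @rdname spectrum
#' @param ds a `spectral_dataset`
#' @export
n_spectra <- function(ds) ncol(ds$intensities)

#' @rdname spectrum
#' @param i spectrum index
#' @export
get_spectrum <- function(ds, i) spectrum(ds$wavenumbers, ds$intensities[, i])
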