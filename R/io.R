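#' Read and write the spectral CSV format
#'
#' Spectra travel as a CSV whose first column is `wavenumber_cm1` and whose
#' remaining columns hold one spectrum each (column name = spectrum id),
#' accompanied by a labels CSV with one row per spectrum (`spectrum_id`,
#' `concentration_mM`, `day`, `sample_id`, ...).
#'
#' @param ds a [spectral_dataset()]
#' @param path path of the spectra CSV
#' @param labels_path path of the labels CSV (default: `path` with a
#'   `_labels.csv` suffix)
#' @return `write_spectra_csv()` returns `path` invisibly;
#'   `read_spectra_csv()` returns a [spectral_dataset()].
#' @export
write_spectra_csv <- function(ds, path, labels_path = default_labels_path(path)) {
  df <- data.frame(wavenumber_cm1 = ds$wavenumbers, ds$intensities,
                   check.names = FALSE)
  utils::write.csv(df, path, row.names = FALSE)
  utils::write.csv(ds$labels, labels_path, row.names = FALSE)
  invisible(path)
}

default_labels_path <- function(path) sub("\\.csv$", "_labels.csv", path)

#' @rdname write_spectra_csv
#' @export
read_spectra_csv <- function(path, labels_path = default_labels_path(path)) {
  df <- utils::read.csv(path, check.names = FALSE)
  if (names(df)[1] != "wavenumber_cm1")
    stop("first column of a spectra CSV must be 'wavenumber_cm1'")
  labels <- utils::read.csv(labels_path)
  spectral_dataset(df[[1]], as.matrix(df[-1]), labels)
}

#' Read and write multiphoton image pairs as 16-bit TIFF
#'
#' Each channel is one single-channel 16-bit TIFF (`<stem>_tpef.tif`,
#' `<stem>_shg.tif`). Intensities are stored as counts in 0..65535; a JSON
#' sidecar (`<stem>.json`) records the pixel size, the intensity scale
#' (counts per intensity unit, so floating-point values round-trip), the
#' generating preset and the seed.
#'
#' @param img a [multimodal_image()]
#' @param stem path stem (no extension) for the three files
#' @return `write_image_pair()` returns `stem` invisibly;
#'   `read_image_pair()` returns a [multimodal_image()] with intensities
#'   promoted to floating point.
#' @export
write_image_pair <- function(img, stem) {
  top <- max(img$tpef, img$shg, 1e-12)
  scale <- 65535 / top
  tiff::writeTIFF(img$tpef / top, paste0(stem, "_tpef.tif"),
                  bits.per.sample = 16)
  tiff::writeTIFF(img$shg / top, paste0(stem, "_shg.tif"),
                  bits.per.sample = 16)
  meta <- img$meta
  meta$preset <- unclass(meta$preset)
  jsonlite::write_json(list(pixel_um = img$pixel_um, scale = scale,
                            meta = meta),
                       paste0(stem, ".json"), auto_unbox = TRUE, digits = NA)
  invisible(stem)
}

#' @rdname write_image_pair
#' @export
read_image_pair <- function(stem) {
  side <- jsonlite::read_json(paste0(stem, ".json"), simplifyVector = TRUE)
  tpef <- tiff::readTIFF(paste0(stem, "_tpef.tif")) * 65535 / side$scale
  shg <- tiff::readTIFF(paste0(stem, "_shg.tif")) * 65535 / side$scale
  multimodal_image(tpef, shg, side$pixel_um,
                   meta = if (is.null(side$meta)) list() else side$meta)
}

#' Read and write topographies as plain-text matrices
#'
#' Heights (nm) as a whitespace-delimited matrix, one scan line per text
#' row, with a JSON sidecar (`<path>.json`) holding `pixel_nm` and the
#' generator seed if known.
#'
#' @param t a [topography()]
#' @param path path of the matrix file
#' @return `write_topography()` returns `path` invisibly;
#'   `read_topography()` returns a [topography()].
#' @export
write_topography <- function(t, path) {
  utils::write.table(t$heights, path, row.names = FALSE, col.names = FALSE)
  seed <- t$meta$config$seed
  jsonlite::write_json(list(pixel_nm = t$pixel_nm,
                            seed = if (is.null(seed)) NA else seed),
                       paste0(path, ".json"), auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_topography
#' @export
read_topography <- function(path) {
  h <- as.matrix(utils::read.table(path))
  dimnames(h) <- NULL
  side <- jsonlite::read_json(paste0(path, ".json"), simplifyVector = TRUE)
  topography(h, side$pixel_nm,
             meta = if (is.null(side$seed) || is.na(side$seed)) list()
                    else list(config = list(seed = side$seed)))
}
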