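#' Random ROI sampling on a two-channel image
#'
#' Draws `n` square regions of interest with top-left corners uniform over
#' all valid positions (0-based, row-major; an ROI covers the half-open
#' pixel ranges `[row, row + size) x [col, col + size)`). Overlap between
#' ROIs is permitted by default; `no_overlap = TRUE` rejection-samples
#' non-overlapping placements instead.
#'
#' @param img a [multimodal_image()]
#' @param n number of ROIs (default 10)
#' @param size ROI side length in pixels (default 100)
#' @param seed integer seed
#' @param no_overlap forbid overlapping ROIs (rejection sampling)
#' @return data.frame with 0-based `row`, `col` and the `size`
#' @export
sample_rois <- function(img, n = 10, size = 100, seed = 0,
                        no_overlap = FALSE) {
  h <- nrow(img$tpef); w <- ncol(img$tpef)
  if (h < size || w < size)
    stop(sprintf("image (%d x %d) smaller than ROI size %d", h, w, size))
  set.seed(seed)
  if (!no_overlap) {
    rows <- sample.int(h - size + 1L, n, replace = TRUE) - 1L
    cols <- sample.int(w - size + 1L, n, replace = TRUE) - 1L
  } else {
    rows <- integer(0); cols <- integer(0)
    tries <- 0L
    while (length(rows) < n) {
      r <- sample.int(h - size + 1L, 1L) - 1L
      cc <- sample.int(w - size + 1L, 1L) - 1L
      ok <- all(abs(r - rows) >= size | abs(cc - cols) >= size)
      if (ok) { rows <- c(rows, r); cols <- c(cols, cc) }
      tries <- tries + 1L
      if (tries > 10000L)
        stop("could not place non-overlapping ROIs (image too small?)")
    }
  }
  data.frame(row = rows, col = cols, size = size)
}

#' Per-ROI mean channel intensities
#'
#' @param img a [multimodal_image()]
#' @param rois data.frame from [sample_rois()]
#' @return data.frame with per-ROI `I_tpef` and `I_shg` (arithmetic means
#'   over the ROI pixels)
#' @export
roi_means <- function(img, rois) {
  n <- nrow(rois)
  out <- data.frame(I_tpef = numeric(n), I_shg = numeric(n))
  for (i in seq_len(n)) {
    rr <- (rois$row[i] + 1L):(rois$row[i] + rois$size[i])
    cc <- (rois$col[i] + 1L):(rois$col[i] + rois$size[i])
    if (max(rr) > nrow(img$tpef) || max(cc) > ncol(img$tpef) ||
        min(rr) < 1L || min(cc) < 1L)
      stop("ROI extends outside the image")
    out$I_tpef[i] <- mean(img$tpef[rr, cc])
    out$I_shg[i] <- mean(img$shg[rr, cc])
  }
  out
}

#' TPEF and SHG intensity ratios over sampled ROIs
#'
#' Averages the per-ROI mean channel intensities across ROIs and forms
#' \deqn{TPEF\ ratio = I_{TPEF} / (I_{SHG} + I_{TPEF}), \quad
#'       SHG\ ratio = I_{SHG} / (I_{SHG} + I_{TPEF}),}
#' i.e. a ratio of means: the ratio is taken on the ROI-averaged
#' intensities, matching the ratio equations operating on mean
#' intensities. The per-ROI ratios (mean of ratios) are also returned as a
#' diagnostic. By construction `tpef_ratio + shg_ratio = 1` and both lie
#' in [0, 1] for non-negative images.
#'
#' @param img a [multimodal_image()]
#' @param rois data.frame from [sample_rois()]
#' @return a `ratio_result`: `I_tpef`, `I_shg` (ROI-averaged means),
#'   `tpef_ratio`, `shg_ratio`, `per_roi` (per-ROI means and ratios),
#'   `mean_of_ratios`
#' @export
compute_ratios <- function(img, rois) {
  pr <- roi_means(img, rois)
  It <- mean(pr$I_tpef)
  Is <- mean(pr$I_shg)
  if (It + Is <= 0) stop("zero total intensity: ratio undefined")
  pr$tpef_ratio <- pr$I_tpef / (pr$I_tpef + pr$I_shg)
  structure(list(I_tpef = It, I_shg = Is,
                 tpef_ratio = It / (Is + It),
                 shg_ratio = Is / (Is + It),
                 per_roi = pr,
                 mean_of_ratios = mean(pr$tpef_ratio)),
            class = "ratio_result")
}

#' @export
print.ratio_result <- function(x, ...) {
  cat(sprintf("<ratio_result: TPEF %.4f, SHG %.4f (n ROI = %d)>\n",
              x$tpef_ratio, x$shg_ratio, nrow(x$per_roi)))
  invisible(x)
}

#' Ratio profiles over a concentration x day series
#'
#' Computes the ROI-based TPEF/SHG ratios for every image and aggregates
#' them per (day, concentration) group: mean and sample sd of the
#' per-image TPEF ratios. Each image gets its own ROI sub-seed
#' ([sub_seed()]) so the series is reproducible from one seed. Groups are
#' read from each image's `meta$preset`; images without a preset need an
#' explicit `groups` table. Empty groups are skipped with a warning.
#'
#' @param images list of [multimodal_image()]
#' @param n,size ROIs per image and ROI side (defaults 10 and 100)
#' @param seed top-level seed for ROI sampling
#' @param groups optional data.frame with `concentration_mM` and `day` per
#'   image, overriding image metadata
#' @return data.frame ordered by day then concentration with columns
#'   `day`, `concentration_mM`, `n_images`, `tpef_ratio`, `tpef_sd`,
#'   `shg_ratio`, `shg_sd`
#' @export
ratio_series <- function(images, n = 10, size = 100, seed = 0,
                         groups = NULL) {
  if (is.null(groups)) {
    groups <- do.call(rbind, lapply(images, function(im) {
      p <- im$meta$preset
      if (is.null(p)) stop("image without preset metadata: supply `groups`")
      data.frame(concentration_mM = p$concentration_mM, day = p$day)
    }))
  }
  stopifnot(nrow(groups) == length(images))
  ratios <- vapply(seq_along(images), function(i) {
    rois <- sample_rois(images[[i]], n, size, seed = sub_seed(seed, i))
    compute_ratios(images[[i]], rois)$tpef_ratio
  }, numeric(1))
  key <- split(seq_along(images),
               list(day = groups$day, conc = groups$concentration_mM),
               drop = TRUE)
  rows <- lapply(key, function(idx) {
    data.frame(day = groups$day[idx[1]],
               concentration_mM = groups$concentration_mM[idx[1]],
               n_images = length(idx),
               tpef_ratio = mean(ratios[idx]),
               tpef_sd = if (length(idx) > 1) stats::sd(ratios[idx]) else NA_real_,
               shg_ratio = 1 - mean(ratios[idx]),
               shg_sd = if (length(idx) > 1) stats::sd(ratios[idx]) else NA_real_)
  })
  out <- do.call(rbind, rows)
  out <- out[order(out$day, out$concentration_mM), , drop = FALSE]
  rownames(out) <- NULL
  out
}
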