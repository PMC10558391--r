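const_image <- function(tpef_val, shg_val, n = 120) {
  multimodal_image(matrix(tpef_val, n, n), matrix(shg_val, n, n),
                   pixel_um = 0.11)
}

test_that("ROI sampling stays in bounds, is deterministic, collapses when forced", {
  img <- const_image(1, 1, 256)
  rois <- sample_rois(img, n = 10, size = 100, seed = 3)
  expect_equal(nrow(rois), 10)
  expect_true(all(rois$row >= 0 & rois$row + 100 <= 256))
  expect_true(all(rois$col >= 0 & rois$col + 100 <= 256))
  expect_identical(rois, sample_rois(img, n = 10, size = 100, seed = 3))
  expect_false(identical(rois, sample_rois(img, n = 10, size = 100, seed = 4)))

  one <- const_image(1, 1, 100)
  forced <- sample_rois(one, n = 5, size = 100, seed = 1)
  expect_true(all(forced$row == 0) && all(forced$col == 0))
  expect_error(sample_rois(const_image(1, 1, 120), size = 200), "smaller")
})

test_that("non-overlapping ROI option yields disjoint ROIs", {
  img <- const_image(1, 1, 500)
  rois <- sample_rois(img, n = 6, size = 100, seed = 2, no_overlap = TRUE)
  for (i in 1:5) for (j in (i + 1):6) {
    expect_true(abs(rois$row[i] - rois$row[j]) >= 100 ||
                abs(rois$col[i] - rois$col[j]) >= 100)
  }
})

test_that("ROI means and ratios are exact on constant and patterned fields", {
  img <- const_image(6, 4)
  rois <- sample_rois(img, n = 4, size = 100, seed = 1)
  pr <- roi_means(img, rois)
  expect_true(all(pr$I_tpef == 6) && all(pr$I_shg == 4))
  rr <- compute_ratios(img, rois)
  expect_equal(rr$tpef_ratio, 0.6)
  expect_equal(rr$shg_ratio, 0.4)

  # checkerboard averages to half its amplitude over a 100x100 ROI
  n <- 120
  cb <- outer(1:n, 1:n, function(i, j) 10 * ((i + j) %% 2))
  img2 <- multimodal_image(cb, matrix(5, n, n), pixel_um = 0.11)
  pr2 <- roi_means(img2, data.frame(row = 0, col = 0, size = 100))
  expect_equal(pr2$I_tpef, 5)

  # equal channels give exactly one half
  img3 <- const_image(2.5, 2.5)
  rr3 <- compute_ratios(img3, sample_rois(img3, 3, 100, seed = 1))
  expect_equal(rr3$tpef_ratio, 0.5)
})

test_that("ratios sum to one, are scale invariant and bounded", {
  cfg <- tiny_image_cfg(seed = 6)
  img <- generate_image_pair(cfg, glycation_preset(100, 30))
  rois <- sample_rois(img, 10, 100, seed = 0)
  rr <- compute_ratios(img, rois)
  expect_identical(rr$tpef_ratio + rr$shg_ratio, 1)
  expect_true(rr$tpef_ratio >= 0 && rr$tpef_ratio <= 1)
  scaled <- multimodal_image(img$tpef * 37.5, img$shg * 37.5, img$pixel_um)
  rr2 <- compute_ratios(scaled, rois)
  expect_equal(rr2$tpef_ratio, rr$tpef_ratio, tolerance = 1e-12)
  zero <- const_image(0, 0)
  expect_error(compute_ratios(zero, sample_rois(zero, 2, 100, seed = 1)),
               "zero total intensity")
})

test_that("noiseless generated images match the closed-form expected ratio", {
  for (g in c(0, 0.26, 0.5)) {
    cfg <- image_gen_config(size_px = 400, noise_sd = 0, seed = 8)
    p <- glycation_preset(200, 30, fluor_transfer_g = g, effect_scale = 1)
    img <- generate_image_pair(cfg, p)
    full <- mean(img$tpef) / (mean(img$tpef) + mean(img$shg))
    expect_equal(full, expected_tpef_ratio(g), tolerance = 1e-6)
  }
})

test_that("ratio series orders groups and tracks the transfer fraction", {
  images <- list()
  i <- 0
  for (d in c(20, 10)) for (cc in c(50, 0, 200)) {
    i <- i + 1
    cfg <- tiny_image_cfg(seed = 50 + i, noise_sd = 10)
    images[[i]] <- generate_image_pair(cfg, glycation_preset(cc, d))
  }
  tab <- ratio_series(images, n = 6, size = 100, seed = 2)
  expect_equal(tab$day, rep(c(10, 20), each = 3))
  expect_equal(tab$concentration_mM, rep(c(0, 50, 200), 2))
  for (d in c(10, 20)) {
    sub <- tab[tab$day == d, ]
    expect_true(all(diff(sub$tpef_ratio) > 0))
  }
  expect_equal(tab$tpef_ratio + tab$shg_ratio, rep(1, 6))
})

test_that("groups of identical constant images have zero spread", {
  imgs <- list(const_image(3, 1), const_image(3, 1))
  tab <- ratio_series(imgs, n = 3, size = 100, seed = 1,
                      groups = data.frame(concentration_mM = c(0, 0),
                                          day = c(10, 10)))
  expect_equal(tab$tpef_sd, 0)
  expect_equal(tab$tpef_ratio, 0.75)
})
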