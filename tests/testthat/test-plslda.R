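# small preprocessed dataset builder used across the classifier tests
make_classed_dataset <- function(day = 30, n_per_class = 12, seed = 21,
                                 noise_sd = 0.01,
                                 concentrations = c(0, 5, 50, 100, 200)) {
  cfg <- raman_gen_config(noise_sd = noise_sd, seed = seed)
  presets <- lapply(concentrations, glycation_preset, day = day)
  ds <- generate_raman_dataset(cfg, presets, n_per_class)
  preprocess_dataset(ds, collagen_reference_spectrum(cfg))
}

test_that("a separable synthetic 5-class set is resubstituted perfectly", {
  pp <- make_classed_dataset(n_per_class = 8, noise_sd = 0.001)
  # widely spaced effects, no heterogeneity: classes are cleanly separable
  m <- fit_plslda(pp, n_components = 8)
  pred <- predict(m, pp)
  truth <- factor(pp$labels$concentration_mM)
  expect_gt(mean(pred == truth), 0.95)
})

test_that("single-class datasets are rejected", {
  pp <- make_classed_dataset(n_per_class = 6, concentrations = 0)
  expect_error(fit_plslda(pp), "two classes")
})

test_that("sample order does not change the fitted discriminant subspace", {
  pp <- make_classed_dataset(n_per_class = 6)
  m1 <- fit_plslda(pp, n_components = 6)
  set.seed(5)
  perm <- sample(n_spectra(pp))
  pp2 <- spectral_dataset(pp$wavenumbers, pp$intensities[, perm],
                          pp$labels[perm, ])
  m2 <- fit_plslda(pp2, n_components = 6)
  l1 <- ld_loadings(m1)$loadings[, 1]
  l2 <- ld_loadings(m2)$loadings[, 1]
  expect_equal(abs_cosine(l1, l2), 1, tolerance = 1e-6)
  expect_equal(as.character(predict(m2, pp)), as.character(predict(m1, pp)))
})

test_that("LD1 loading localizes at the band that separates the classes", {
  # two classes differing only through the broad 1372 cm^-1 band
  cfg <- raman_gen_config(noise_sd = 0.005, effect_jitter_sd = 0, seed = 31)
  w <- seq(cfg$axis_lo, cfg$axis_hi, by = cfg$axis_step)
  base <- make_collagen_bands()
  set.seed(31)
  mk <- function(amp1372, n) {
    sapply(seq_len(n), function(i) {
      bands <- c(base, list(band_spec(1372, 30, amp1372)))
      lorentzian_sum(w, bands) + rnorm(length(w), 0, 0.005)
    })
  }
  X <- cbind(mk(0, 15), mk(0.3, 15))
  ds <- spectral_dataset(w, X, data.frame(concentration_mM = rep(c(0, 200), each = 15),
                                          day = 30, sample_id = 1))
  pp <- preprocess_dataset(ds, collagen_reference_spectrum(cfg))
  m <- fit_plslda(pp, n_components = 5)
  ld <- ld_loadings(m)
  peak_w <- ld$wavenumbers[which.max(abs(ld$loadings[, 1]))]
  expect_lte(abs(peak_w - 1372), 10)
  expect_equal(ld$wavenumbers, pp$wavenumbers)
  # sign convention: the largest-magnitude element is positive
  expect_gt(ld$loadings[which.max(abs(ld$loadings[, 1])), 1], 0)
})

test_that("confusion metrics match hand-computed values", {
  perfect <- diag(c(20, 20, 20, 20, 20))
  rownames(perfect) <- colnames(perfect) <- letters[1:5]
  m <- confusion_metrics(perfect)
  expect_equal(unname(m$sensitivity), rep(1, 5))
  expect_equal(unname(m$specificity), rep(1, 5))
  expect_equal(m$accuracy, 1)

  two <- matrix(c(8, 2, 4, 6), 2, 2, byrow = TRUE)
  m2 <- confusion_metrics(two)
  expect_equal(unname(m2$sensitivity), c(0.8, 0.6))
  expect_equal(unname(m2$specificity), c(0.6, 0.8))
  expect_equal(m2$accuracy, 0.7)

  onecol <- matrix(c(5, 0, 7, 0), 2, 2, byrow = TRUE)
  m3 <- confusion_metrics(onecol)
  expect_equal(unname(m3$sensitivity), c(1, 0))
  expect_error(confusion_metrics(matrix(1:6, 2, 3)), "square")
})

test_that("zero-row confusion warns and reports NA sensitivity", {
  conf <- matrix(c(0, 0, 3, 7), 2, 2, byrow = TRUE)
  expect_warning(m <- confusion_metrics(conf), "undefined")
  expect_true(is.na(m$sensitivity[1]))
})

test_that("stratified CV is deterministic and conserves class counts", {
  pp <- make_classed_dataset(n_per_class = 10)
  cv1 <- kfold_cv(pp, k = 5, n_components = 6, seed = 7)
  cv2 <- kfold_cv(pp, k = 5, n_components = 6, seed = 7)
  expect_identical(cv1, cv2)
  expect_equal(unname(rowSums(cv1$confusion)), rep(10, 5))
  # stratification: every fold holds 2 of each class
  tab <- table(cv1$fold_assignments, pp$labels$concentration_mM)
  expect_true(all(tab == 2))
  # pooled accuracy equals the fold-size-weighted mean of fold accuracies
  expect_equal(cv1$accuracy, mean(cv1$fold_accuracy), tolerance = 1e-12)
  cv3 <- kfold_cv(pp, k = 5, n_components = 6, seed = 8)
  expect_false(identical(cv1$fold_assignments, cv3$fold_assignments))
})

test_that("classes smaller than k are rejected", {
  pp <- make_classed_dataset(n_per_class = 3)
  expect_error(kfold_cv(pp, k = 5), "at least k")
})

test_that("accuracy grows with the glycation effect scale", {
  accs <- vapply(c(10, 20, 30), function(d) {
    pp <- make_classed_dataset(day = d, n_per_class = 20, seed = 40 + d)
    kfold_cv(pp, k = 5, n_components = 8, seed = 1)$accuracy
  }, numeric(1))
  expect_true(all(diff(accs) > 0))
})
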