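test_that("crop keeps the closed fingerprint interval and is a projection", {
  s <- spectrum(seq(400, 1800, by = 2), seq_along(seq(400, 1800, by = 2)))
  cr <- crop_fingerprint(s)
  expect_equal(range(cr$wavenumbers), c(800, 1750))
  expect_identical(crop_fingerprint(cr), cr)
  already <- spectrum(seq(800, 1750, by = 2), rnorm(length(seq(800, 1750, by = 2))))
  expect_identical(crop_fingerprint(already), already)
  expect_error(crop_fingerprint(spectrum(200:600, rep(1, 401))), "overlap")
})

test_that("hat basis has full rank, unit maxima and the closed-form endpoints", {
  ref <- collagen_reference_spectrum(raman_gen_config(axis_lo = 800,
                                                      axis_hi = 1750,
                                                      axis_step = 1))
  B <- build_emsc_basis(ref, 5)
  expect_equal(dim(B), c(length(ref$wavenumbers), 5))
  expect_equal(qr(B)$rank, 5)
  expect_equal(unname(apply(B, 2, max)), rep(1, 5))
  # hat i peaks at knot i and vanishes at the other knots
  knots <- seq(800, 1750, length.out = 5)
  w <- ref$wavenumbers
  for (i in 1:5) {
    ki <- which.min(abs(w - knots[i]))
    expect_equal(B[ki, i], 1, tolerance = 0.005)  # knots can fall off-grid
    for (j in setdiff(1:5, i)) {
      kj <- which.min(abs(w - knots[j]))
      expect_lt(B[kj, i], 0.005)
    }
  }
  # the hat span contains every global linear baseline
  for (target in list(rep(1, length(w)), 0.5 + 0.002 * w)) {
    fit <- lm.fit(B, target)
    expect_lt(max(abs(fit$residuals)), 1e-10)
  }
  expect_equal(ncol(build_emsc_basis(ref, 1)), 1)
  expect_true(all(build_emsc_basis(ref, 1) == 1))
  expect_error(build_emsc_basis(ref, 0), "n_background")
})

test_that("polynomial basis option is full rank with unit max columns", {
  ref <- collagen_reference_spectrum(raman_gen_config())
  B <- build_emsc_basis(ref, 5, type = "poly")
  expect_equal(qr(B)$rank, 5)
  expect_equal(unname(apply(abs(B), 2, max)), rep(1, 5))
})

test_that("EMSC self-fit is the identity and span inputs are recovered exactly", {
  ref <- crop_fingerprint(collagen_reference_spectrum(raman_gen_config()))
  B <- build_emsc_basis(ref, 5)
  fit <- emsc_correct(ref, ref, B)
  expect_equal(fit$b, 1, tolerance = 1e-10)
  expect_equal(fit$a, rep(0, 5), tolerance = 1e-8)
  expect_equal(fit$corrected$intensities, ref$intensities, tolerance = 1e-10)

  # 2 * reference + linear ramp: exact recovery, b = 2
  w <- ref$wavenumbers
  ramp <- 0.4 + 0.002 * (w - min(w))
  s <- spectrum(w, 2 * ref$intensities + ramp)
  fit2 <- emsc_correct(s, ref, B)
  expect_equal(fit2$b, 2, tolerance = 1e-10)
  expect_equal(fit2$corrected$intensities, ref$intensities, tolerance = 1e-8)
  expect_lt(fit2$residual_norm, 1e-8)
})

test_that("EMSC coefficients match an independent pseudoinverse oracle", {
  ref <- crop_fingerprint(collagen_reference_spectrum(raman_gen_config()))
  B <- build_emsc_basis(ref, 5)
  D <- cbind(ref$intensities, B)
  set.seed(101)
  for (i in 1:50) {
    y <- runif(1, 0.5, 3) * ref$intensities +
      B %*% rnorm(5, 0, 0.5) + rnorm(nrow(B), 0, 0.05)
    fit <- emsc_correct(spectrum(ref$wavenumbers, y), ref, B)
    oracle <- as.numeric(pinv_solve(D, y))
    expect_equal(c(fit$b, fit$a), oracle, tolerance = 1e-10)
  }
})

test_that("normalization scales by the window maximum and is idempotent", {
  w <- seq(800, 1750, by = 1)
  s <- spectrum(w, rep(5, length(w)))
  ns <- normalize_at(s)
  expect_equal(max(ns$intensities[w >= 1446 & w <= 1456]), 1)
  expect_equal(ns$intensities, s$intensities / 5)
  expect_equal(normalize_at(ns), ns)
  # synthetic collagen spectrum: anchor peak is exactly 1 after normalization
  ref <- crop_fingerprint(collagen_reference_spectrum(raman_gen_config()))
  nref <- normalize_at(ref)
  win <- nref$wavenumbers >= 1446 & nref$wavenumbers <= 1456
  expect_equal(max(nref$intensities[win]), 1)
  expect_error(normalize_at(spectrum(w, rep(0, length(w)))), "anchor")
  expect_error(normalize_at(spectrum(seq(800, 900), rep(1, 101))), "window")
})

test_that("preprocess_dataset maps reference copies to the normalized reference", {
  cfg <- raman_gen_config()
  ref <- collagen_reference_spectrum(cfg)
  w <- ref$wavenumbers
  X <- cbind(ref$intensities, 3 * ref$intensities + 0.5,
             0.7 * ref$intensities - 0.001 * (w - 600))
  ds <- spectral_dataset(w, X, data.frame(concentration_mM = c(0, 0, 0),
                                          day = 30, sample_id = 1))
  pp <- preprocess_dataset(ds, ref)
  target <- normalize_at(crop_fingerprint(ref))$intensities
  for (i in 1:3)
    expect_equal(pp$intensities[, i], target, tolerance = 1e-8)
  log <- attr(pp, "preproc_log")
  expect_equal(log$b, c(1, 3, 0.7), tolerance = 1e-8)
})

test_that("a corrupt all-zero spectrum is reported by id", {
  cfg <- raman_gen_config(seed = 2)
  ds <- generate_raman_dataset(cfg, list(glycation_preset(0, 30)), 3)
  ds$intensities[, 2] <- 0
  ref <- collagen_reference_spectrum(cfg)
  expect_error(preprocess_dataset(ds, ref), "s0002")
})

test_that("preprocessing a seeded synthetic dataset is deterministic", {
  cfg <- raman_gen_config(seed = 8)
  ref <- collagen_reference_spectrum(cfg)
  ds <- generate_raman_dataset(cfg, list(glycation_preset(50, 20)), 4)
  expect_identical(preprocess_dataset(ds, ref)$intensities,
                   preprocess_dataset(ds, ref)$intensities)
})
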