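test_that("baseline fit reproduces polynomial and constant inputs", {
  x <- flat_axis(400)
  u <- (x - mean(x)) / diff(range(x)) * 2
  y_poly <- 3 + 0.5 * u - 2 * u^2 + u^3 + 0.2 * u^4 - 0.7 * u^5
  bl <- fit_baseline(raman_spectrum(x, y_poly))
  expect_equal(bl$intensities, y_poly, tolerance = 1e-6)

  bl10 <- fit_baseline(raman_spectrum(x, rep(10, length(x))))
  expect_equal(bl10$intensities, rep(10, length(x)), tolerance = 1e-8)

  expect_error(fit_baseline(raman_spectrum(1:10, 1:10)), "anchors")
})

test_that("baseline subtraction recovers generated band heights within 5%", {
  cfg <- quiet_config(seed = 2, noise_sd = 0.003)
  coh <- generate_cohort(cfg)
  cat <- cfg$peak_catalog
  # isolated strong bands, away from overlapping neighbours
  probe <- c(441, 621, 1001)
  for (i in c(1L, 4L)) {
    sp <- coh$set$spectra[[i]]
    # the polynomial fit absorbs both the fluorescence-like background and
    # the smooth substrate, leaving the bands
    corr <- subtract_baseline(sp, fit_baseline(sp))
    truth <- coh$truth$amplitudes[i, ]
    for (p in probe) {
      got <- corr$intensities[which.min(abs(sp$shifts - p))]
      expect_lt(abs(got - truth[[as.character(p)]]) / truth[[as.character(p)]],
                0.05)
    }
  }
})

test_that("baseline subtraction obeys its algebra and error contracts", {
  x <- flat_axis(100)
  sp <- raman_spectrum(x, rnorm(100))
  expect_equal(subtract_baseline(sp, sp)$intensities, rep(0, 100))
  zero <- raman_spectrum(x, rep(0, 100))
  expect_equal(subtract_baseline(sp, zero)$intensities, sp$intensities)
  other <- raman_spectrum(x + 1, rep(0, 100))
  expect_error(subtract_baseline(sp, other), "axis")
})

test_that("Savitzky-Golay smoothing reproduces quadratics and attenuates spikes", {
  x <- flat_axis(101)
  y_quad <- 2 + 0.1 * x + 0.001 * x^2
  sm <- sg_smooth(raman_spectrum(x, y_quad))
  expect_equal(sm$intensities, y_quad, tolerance = 1e-8)

  y_const <- rep(3, 101)
  expect_equal(sg_smooth(raman_spectrum(x, y_const))$intensities, y_const)

  # single spike of height h on a flat signal, 9-point quadratic filter:
  # central coefficient c0 = 3(3m^2 + 3m - 1) / ((2m-1)(2m+1)(2m+3)), m = 4
  h <- 10
  y_spike <- rep(0, 101)
  y_spike[51] <- h
  sm <- sg_smooth(raman_spectrum(x, y_spike))
  c0 <- 3 * (3 * 16 + 12 - 1) / (7 * 9 * 11)  # = 59/231
  expect_equal(sm$intensities[51], c0 * h, tolerance = 1e-10)

  expect_error(preprocess_config(sg_window = 8), "odd")
  expect_error(preprocess_config(sg_window = 1), "odd|greater")
})

test_that("reference-band normalization fixes the window maximum at 1", {
  x <- flat_axis(1501)
  y <- gaussian_band(x, 1001, 4, 2) + gaussian_band(x, 850, 4, 5) + 0.1
  sp <- raman_spectrum(x, y)
  nm <- normalize_to_reference(sp)
  idx <- which(abs(x - 1001.5) <= 4)
  expect_equal(max(nm$intensities[idx]), 1)

  # scale invariance
  nm2 <- normalize_to_reference(raman_spectrum(x, 37.3 * y))
  expect_equal(nm$intensities, nm2$intensities, tolerance = 1e-12)

  neg <- raman_spectrum(x, y - 10)
  expect_error(normalize_to_reference(neg), "artifact")
})

test_that("resampling yields the 985-point grid and is exact on linear signals", {
  x <- seq(400, 1600, by = 0.8)
  sp <- raman_spectrum(x, 0.5 * x + 3)
  rs <- resample_spectrum(sp)
  expect_length(rs$intensities, 985L)
  expect_equal(diff(rs$shifts), rep(0.98, 984), tolerance = 1e-12)
  expect_equal(rs$intensities, 0.5 * rs$shifts + 3, tolerance = 1e-9)

  cst <- resample_spectrum(raman_spectrum(x, rep(2, length(x))))
  expect_true(all(cst$intensities == 2))

  short <- raman_spectrum(seq(500, 900, by = 0.8),
                          rep(1, length(seq(500, 900, by = 0.8))))
  expect_error(resample_spectrum(short), "beyond")
})

test_that("substrate subtraction recovers an additively constructed signal", {
  cfg5 <- tiny_config(substrate_amplitude = 0.4)
  sub <- generate_substrate_spectrum(cfg5)
  x <- sub$shifts
  signal <- gaussian_band(x, 1001, 4, 1) + gaussian_band(x, 620, 5, 0.5)
  sp <- raman_spectrum(x, signal + sub$intensities)
  out <- subtract_substrate(sp, sub)
  expect_equal(out$intensities, signal, tolerance = 1e-12)

  zero <- raman_spectrum(x, rep(0, length(x)))
  expect_equal(subtract_substrate(sp, zero)$intensities, sp$intensities)
  expect_error(subtract_substrate(sp, raman_spectrum(x + 1, sub$intensities)),
               "mismatch")
})

test_that("least-squares substrate scale is close to 1 on generator data", {
  cfg <- quiet_config(seed = 9, noise_sd = 0.002, substrate_amplitude = 0.3)
  coh <- generate_cohort(cfg)
  cat <- cfg$peak_catalog
  x <- coh$set$spectra[[1L]]$shifts
  u <- 2 * (x - cfg$axis_start) / (cfg$axis_end - cfg$axis_start) - 1
  upow <- vapply(0:5, function(k) u^k, numeric(length(u)))
  lsq_cfg <- preprocess_config(substrate_scale_mode = "lsq")
  peak_free <- vapply(x, function(xx) all(abs(xx - cat$center) > 25), TRUE)
  for (i in c(1L, 8L)) {
    true_bl <- drop(upow %*% coh$truth$baseline_coefficients[i, ])
    sp <- coh$set$spectra[[i]]
    corr <- raman_spectrum(x, sp$intensities - true_bl)  # peaks + substrate
    out <- subtract_substrate(corr, coh$truth$substrate, lsq_cfg,
                              peak_free = peak_free)
    expect_lt(abs(attr(out, "substrate_scale") - 1), 0.05)
  }
})

test_that("artifact screening is clean on artifact-free data and partitions the set", {
  coh <- generate_cohort(tiny_config(seed = 10, n_sub = 4L, n_spec = 4L))
  da <- detect_artifacts(coh$set)
  expect_equal(n_spectra(da$kept) + n_spectra(da$rejected), n_spectra(coh$set))
  expect_equal(n_spectra(da$rejected), 0L)
})

test_that("artifact screening flags injected artifacts with high sensitivity and specificity", {
  cfg <- cohort_config(n_subjects_per_group = 15L, spectra_per_subject = 25L,
                       artifact_rate = 0.1, seed = 12)
  coh <- generate_cohort(cfg)
  expect_equal(n_spectra(coh$set), 750L)
  da <- detect_artifacts(coh$set)
  truth_art <- coh$truth$records$artifact != "none"
  sens <- mean(da$stats$rejected[truth_art])
  spec <- mean(!da$stats$rejected[!truth_art])
  expect_gte(sens, 0.95)
  expect_gte(spec, 0.95)
})

test_that("the full chain preserves clean cohorts and lands on the 985-point grid", {
  cfg <- quiet_config(seed = 3, noise_sd = 0.005)
  coh <- generate_cohort(cfg)
  sub <- generate_substrate_spectrum(cfg)
  pp <- preprocess_pipeline(coh$set, substrate = sub)
  expect_equal(n_spectra(pp$processed), n_spectra(coh$set))
  expect_true(pp$processed$resampled)
  expect_length(pp$processed$grid, 985L)

  # reference-band convention holds for every output spectrum
  idx <- which(abs(pp$processed$grid - 1001.5) <= 4)
  m <- spectra_matrix(pp$processed)
  expect_equal(unname(apply(m[, idx], 1, max)), rep(1, nrow(m)))
})

test_that("the preprocessing chain is quasi-idempotent", {
  cfg <- quiet_config(seed = 6, noise_sd = 0.005, n_sub = 2L, n_spec = 2L)
  coh <- generate_cohort(cfg)
  sub <- generate_substrate_spectrum(cfg)
  once <- preprocess_pipeline(coh$set, substrate = sub)

  # the baseline of a baseline-corrected spectrum is essentially zero
  for (sp in once$processed$spectra) {
    bl2 <- fit_baseline(sp)
    expect_lt(max(abs(bl2$intensities)), 0.03)
  }

  # a second full application leaves the spectra nearly unchanged; the
  # residual change is dominated by the second smoothing pass attenuating
  # the narrow reference band (smoothing is not an idempotent operation),
  # which the final rescale propagates as a small global factor
  twice <- preprocess_pipeline(once$processed, substrate = NULL)
  m1 <- spectra_matrix(once$processed)
  m2 <- spectra_matrix(twice$processed)
  for (i in seq_len(nrow(m1))) {
    expect_lt(sqrt(mean((m2[i, ] - m1[i, ])^2)), 0.02)  # on the 0..1 scale
    expect_gt(cor(m1[i, ], m2[i, ]), 0.995)
  }
})

test_that("recovered band-amplitude vectors correlate >= 0.98 with ground truth", {
  cfg <- tiny_config(seed = 13, n_sub = 4L, n_spec = 4L, noise_sd = 0.005,
                     spike_rate = 0)
  coh <- generate_cohort(cfg)
  pp <- preprocess_pipeline(coh$set, generate_substrate_spectrum(cfg))
  grid <- pp$processed$grid
  centers <- cfg$peak_catalog$center
  on_grid <- centers >= min(grid) & centers <= max(grid)
  cols <- vapply(centers[on_grid], function(p) which.min(abs(grid - p)), 0L)
  m <- spectra_matrix(pp$processed)
  for (i in seq_len(nrow(m))) {
    rec <- m[i, cols]
    truth <- coh$truth$amplitudes[i, on_grid]
    expect_gte(cor(rec, truth), 0.98)
  }
})
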