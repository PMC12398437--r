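test_that("healthy reference model reproduces the fatty-breast optical anchor", {
  m <- default_healthy_model()
  expect_equal(absorption_mu_a(m, 786), 0.041, tolerance = 1e-12)
  expect_equal(reduced_scattering(m, 786), 8.5, tolerance = 1e-12)
  wl <- canonical_grid()
  expect_true(all(absorption_mu_a(m, wl) > 0))
  expect_true(all(reduced_scattering(m, wl) > 0))
})

test_that("absorption mixes chromophores linearly over a floor", {
  m <- default_healthy_model()
  wl <- canonical_grid()
  m0 <- m; m0$chromophore_conc[] <- 0; m0$mua_floor <- 0.037
  expect_equal(absorption_mu_a(m0, wl), rep(0.037, length(wl)))
  m2 <- m; m2$chromophore_conc <- 2 * m$chromophore_conc; m2$mua_floor <- 2 * m$mua_floor
  expect_equal(absorption_mu_a(m2, wl), 2 * absorption_mu_a(m, wl))
  expect_error(absorption_mu_a(m, 300), "basis range")
})

test_that("class-conditional sampling is symmetric at zero contrast and shifted at full contrast", {
  cfg0 <- sim_config(class_contrast = 0)
  thb_of <- function(m) sum(m$chromophore_conc[c("oxyHb", "deoxyHb")])
  draw_means <- function(class_label, cfg, n = 4000, seed = 1) {
    set.seed(seed)
    mean(vapply(seq_len(n),
                function(i) thb_of(sample_tissue_model(class_label, cfg)),
                numeric(1)))
  }
  h0 <- draw_means("healthy", cfg0); i0 <- draw_means("IDC", cfg0, seed = 2)
  # identical distributions at contrast 0: means agree to Monte-Carlo error
  expect_lt(abs(h0 - i0) / h0, 0.02)
  # same seed, contrast 0: identical draws
  set.seed(9); a <- sample_tissue_model("healthy", cfg0)
  set.seed(9); b <- sample_tissue_model("ILC", cfg0)
  expect_equal(a$chromophore_conc, b$chromophore_conc)
  cfg1 <- sim_config(class_contrast = 1)
  h1 <- draw_means("healthy", cfg1); i1 <- draw_means("IDC", cfg1, seed = 2)
  expect_gt(i1, h1)  # tumours carry more total haemoglobin by design
  expect_error(sample_tissue_model("bogus", cfg1))
})

test_that("diffusion reflectance decays with absorption and distance, and vanishes in the absorbing limit", {
  m <- default_healthy_model()
  ch05 <- channel_spec("DRS05"); ch28 <- channel_spec("DRS28")
  wl <- canonical_grid()
  expect_gt(drs_forward(m, ch05, 786), drs_forward(m, ch28, 786))
  expect_true(all(drs_forward(m, ch05, wl) > drs_forward(m, ch28, wl)))
  r0 <- drs_forward(m, ch05, 786)
  mhi <- m; mhi$mua_floor <- m$mua_floor + 0.5
  expect_lt(drs_forward(mhi, ch05, 786), r0)
  mext <- m; mext$mua_floor <- 1e3
  expect_lt(suppressWarnings(drs_forward(mext, ch05, 786)), 1e-6)
  expect_error(drs_forward(m, channel_spec("IFS405"), 786), "reflectance")
})

test_that("diffusion forward model matches the numerical Hankel-transform oracle within 1%", {
  m <- default_healthy_model()
  wl <- seq(430, 850, length.out = 10)
  mua <- absorption_mu_a(m, wl)
  musp <- reduced_scattering(m, wl)
  for (ch in c("DRS05", "DRS08", "DRS16", "DRS28")) {
    rho <- channel_spec(ch)$sds_mm / 10
    closed <- drs_forward(m, channel_spec(ch), wl)
    numeric <- vapply(seq_along(wl),
                      function(i) hankel_reflectance(rho, mua[i], musp[i]),
                      numeric(1))
    expect_lt(max(abs(closed - numeric) / numeric), 0.01)
  }
})

test_that("fluorescence forward model honours weights, the long-pass filter, and the argmax oracle", {
  m <- default_healthy_model()
  ch <- channel_spec("IFS375")
  wl <- ch$native_grid
  m0 <- m; for (k in names(m0$fluor_weights)) m0$fluor_weights[[k]][] <- 0
  expect_equal(ifs_forward(m0, ch), rep(0, length(wl)))
  m1 <- m0
  m1$fluor_weights[["375"]]["FAD"] <- 1
  m1$chromophore_conc[] <- 0; m1$mua_floor <- 0
  e <- ifs_forward(m1, ch)
  keep <- wl >= 425
  expect_equal(e[keep], emission_basis(wl)[keep, "FAD"])
  expect_true(all(e[wl < 425] == 0))
  e_def <- ifs_forward(m, ch)
  expect_true(all(e_def >= 0))
  # brute-force argmax scan of the generated curve
  expect_equal(wl[which.max(e_def)], wl[order(e_def, decreasing = TRUE)[1]])
  expect_error(ifs_forward(m, channel_spec("DRS05")), "fluorescence")
})

test_that("instrument model is exact without noise, linear in time, and has the declared variance", {
  ch <- channel_spec("DRS05")
  n <- length(ch$native_grid)
  ideal <- seq(1, 3, length.out = n)
  silent <- noise_params(shot_scale = 0, read_sd = 0, dark_offset = 0)
  flat <- rep(1, n)
  s1 <- instrument_apply(ideal, ch, 1, silent, response = flat)
  expect_equal(s1$counts, ideal)
  s2 <- instrument_apply(ideal, ch, 2, silent, response = flat)
  expect_equal(s2$counts, 2 * ideal)
  expect_error(instrument_apply(ideal, ch, 0, silent), "positive")
  # sample-variance oracle at one wavelength
  np <- noise_params(shot_scale = 2, read_sd = 15, dark_offset = 50)
  set.seed(5)
  reps <- replicate(1e4, instrument_apply(rep(100, 4),
                                          channel_spec("DRS05", c(420, 500, 700, 860)),
                                          1, np, response = rep(1, 4))$counts[2])
  expected_var <- np$shot_scale * (100 + 50) + np$read_sd^2
  expect_lt(abs(stats::var(reps) - expected_var) / expected_var, 0.05)
})

test_that("zero-noise calibration cancels the system response exactly (round trip)", {
  cfg <- sim_config(n_patients = 1, positions_per_side = 1,
                    spectra_noise = noise_params(0, 0, 0), rng_seed = 3)
  ds <- generate_dataset(cfg)
  model_class <- ds$samples$tissue_class[1]
  st <- ds$sets[[1]]
  pr <- preprocess_spectrum(st$spectra$DRS05, ds$calibration)
  # reconstruct the ideal reflectance from the same seeded draw path is not
  # needed: calibrated DRS must be a constant multiple of the forward model
  # for *some* tissue model; check constancy of shape via the white channel
  rate <- correct_integration_time(st$spectra$DRS05, ds$calibration$dark$DRS05)
  ref <- correct_integration_time(ds$calibration$white$DRS05,
                                  ds$calibration$dark$DRS05)
  cal <- calibrate_shape(rate, ref)
  ch <- channel_spec("DRS05", cfg$native_grid)
  resp <- system_response(ch$native_grid, ch)
  implied_ideal <- rate$rate / resp           # counts/s / response
  ratio <- cal$rate / implied_ideal           # should be 1/0.99 everywhere
  expect_equal(ratio, rep(1 / 0.99, length(ratio)), tolerance = 1e-10)
  expect_true(pr$passed_qc)
  # calibration spectra themselves clear the SNR gate under default noise
  set.seed(11)
  cs <- generate_calibration_set()
  wrate <- correct_integration_time(cs$white$DRS08, cs$dark$DRS08)
  expect_gte(compute_snr(wrate$rate), 5)
})

test_that("dataset generation respects the hierarchy, counts and seed determinism", {
  cfg <- sim_config(n_patients = 2, samples_per_patient = c(`1` = 1),
                    positions_per_side = 8, rng_seed = 21)
  ds <- generate_dataset(cfg)
  expect_equal(length(ds$sets), 2 * 2 * 8)      # patients x sides x positions
  expect_equal(sum(ds$samples$n_spectra), 32 * 6)
  expect_true(all(vapply(ds$sets, function(s) length(s$spectra), 0L) == 6L))
  drs_n <- vapply(ds$sets, function(s)
    sum(grepl("^DRS", names(s$spectra))), 0L)
  expect_true(all(drs_n == 4L))
  ds2 <- generate_dataset(cfg)
  expect_identical(ds$samples, ds2$samples)
  expect_identical(ds$sets[[5]]$spectra$IFS405$counts,
                   ds2$sets[[5]]$spectra$IFS405$counts)
  # configured 8-10 positions x 2 sides x 6 channels => 96-120 per sample
  ds3 <- generate_dataset(sim_config(n_patients = 4, rng_seed = 8))
  expect_true(all(ds3$samples$n_spectra >= 96 & ds3$samples$n_spectra <= 120))
})

test_that("quality grading follows the worst-condition rule", {
  expect_equal(grade_quality(10, "none"), 1L)
  expect_equal(grade_quality(10, "heavy"), 3L)
  expect_equal(grade_quality(3.5, "none"), 2L)
  expect_equal(grade_quality(10, "partial"), 2L)
  expect_equal(grade_quality(2.9, "none"), 3L)
  expect_equal(grade_quality(3, "none"), 2L)   # closed boundary [3, 4]
  expect_equal(grade_quality(4, "none"), 2L)
  expect_equal(grade_quality(4.01, "none"), 1L)
  expect_error(grade_quality(-1, "none"), "negative")
  expect_error(grade_quality(5, "soaked"))
})
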