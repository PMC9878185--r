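test_that("von Mises sampler matches the Bessel-ratio resultant length", {
  set.seed(31)
  for (kappa in c(0.5, 2, 8)) {
    th <- rvonmises(20000, kappa)
    expect_lt(abs(Mod(mean(exp(1i * th))) - plv_expected(kappa)), 0.02)
    expect_true(all(th > -pi & th <= pi))
  }
  expect_lt(Mod(mean(exp(1i * rvonmises(20000, 0)))), 0.02)  # uniform
})

test_that("kappa_from_plv inverts plv_expected", {
  rho <- c(0.05, 0.2425, 0.5, 0.6978, 0.9)
  expect_equal(plv_expected(kappa_from_plv(rho)), rho, tolerance = 1e-6)
})

test_that("clinical generator reproduces group sizes and determinism", {
  cfg <- cohort_config(seed = 33)
  df <- generate_clinical(cfg)
  expect_equal(nrow(df), 131)
  expect_equal(sum(df$group == "CON"), 55)
  expect_equal(sum(df$group == "CI"), 76)
  expect_identical(df, generate_clinical(cfg))   # same seed, same table
  expect_false(identical(df,
                         generate_clinical(cohort_config(seed = 34))))
  # records are internally consistent and encodable
  enc <- encode_clinical(df)
  expect_true(all(enc$years_since_onset <= enc$age_y))
})

test_that("a degenerate category probability yields a constant column", {
  spec <- table2_clinical_spec()
  spec$categorical$vpa$CON <- c(0, 1)
  spec$categorical$vpa$CI <- c(0, 1)
  cfg <- cohort_config(n_con = 10, n_ci = 10, clinical_spec = spec,
                       seed = 35)
  expect_true(all(generate_clinical(cfg)$vpa == "Y"))
  spec$categorical$vpa$CON <- c(0.5, 0.6)
  expect_error(generate_clinical(
    cohort_config(n_con = 5, n_ci = 5, clinical_spec = spec)),
    "sum to 1")
})

test_that("coupling configuration is validated", {
  expect_error(cohort_config(couplings = data.frame(
    band = "theta", ch_a = "Fp1", ch_b = "Xx", plv_con = .3, plv_ci = .6,
    subject_sd = 0)), "unknown channel")
  expect_error(cohort_config(couplings = data.frame(
    band = "theta", ch_a = "Fp1", ch_b = "Fp1", plv_con = .3,
    plv_ci = .6, subject_sd = 0)), "distinct")
  expect_error(cohort_config(couplings = data.frame(
    band = "theta", ch_a = c("Fp1", "Fz"), ch_b = c("Fz", "Cz"),
    plv_con = .3, plv_ci = .6, subject_sd = 0)), "disjoint")
})

test_that("waveform generator: near-zero jitter gives pipeline PLV ~ 1", {
  cfg <- cohort_config(
    duration_s = 120, seed = 36,
    couplings = data.frame(band = "theta", ch_a = "Fp1", ch_b = "Fz",
                           plv_con = 0.9999, plv_ci = 0.9999,
                           subject_sd = 0))
  rec <- generate_eeg(cfg, 1, "CON")
  expect_s3_class(rec, "eeg_recording")
  expect_equal(rec$duration_s, 120)
  es <- segment_epochs(broadband_filter(rec), 6)
  pes <- instantaneous_phase(band_decompose(es)$theta)
  ia <- match("Fp1", canonical_channels())
  ib <- match("Fz", canonical_channels())
  plv <- plv_pair(matrix(pes$epochs[ia, , ], dim(pes$epochs)[2]),
                  matrix(pes$epochs[ib, , ], dim(pes$epochs)[2]),
                  rec$sampling_rate_hz, 0.5)
  expect_gte(plv, 0.99)
})

test_that("coupling in theta leaves the pair's other bands at null level", {
  cfg <- cohort_config(
    duration_s = 300, seed = 37,
    couplings = data.frame(band = "theta", ch_a = "Fp1", ch_b = "Fz",
                           plv_con = 0.95, plv_ci = 0.95, subject_sd = 0))
  feats <- extract_plv_features(generate_eeg(cfg, 1, "CON"))$vector
  expect_gt(feats["theta_Fp1-Fz"], 0.8)
  # independence null at N = 50: sqrt(pi / (4 * 50)) ~ 0.125; allow 3 sd
  for (b in c("delta", "alpha", "beta"))
    expect_lt(feats[paste0(b, "_Fp1-Fz")], 0.35)
})

test_that("EDF fixture of a 20-min synthetic subject epochs into 200", {
  cfg <- cohort_config(duration_s = 1200, seed = 38)
  rec <- generate_eeg(cfg, 1, "CI")
  path <- withr::local_tempfile(fileext = ".edf")
  write_fixture_edf(rec, path)
  back <- read_edf(path)
  expect_equal(segment_epochs(back, 6)$n_epochs, 200)
  expect_lt(max(abs(back$data - rec$data)), 2 * 800 / 65535)
  expect_identical(back$channel_labels, rec$channel_labels)
})

test_that("phase-level cohort generator is seeded and labelled", {
  cfg <- cohort_config(n_con = 4, n_ci = 5, seed = 39)
  a <- generate_plv_cohort(cfg, n_epochs = 25)
  b <- generate_plv_cohort(cfg, n_epochs = 25)
  expect_identical(a$table, b$table)
  expect_equal(table(a$table$group)[["CON"]], 4)
  expect_equal(ncol(a$table), 2 + 684)
  expect_setequal(a$implanted,
                  c("theta_T5-T6", "theta_Fp1-Pz", "theta_F4-F7",
                    "theta_C4-P3", "theta_F3-F8"))
  expect_true(all(a$implanted %in% names(a$table)))
})
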