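test_that("instantaneous phase of a cosine advances at its frequency", {
  rate <- 256
  tt <- (seq_len(7 * rate) - 1) / rate
  x <- cos(2 * pi * 5 * tt)
  ph <- Arg(plvdx:::analytic_signal(x))
  core <- (rate + 1):(6 * rate)          # central 5 s
  slope <- diff(unwrap_phase(ph))[core] * rate
  expect_lt(max(abs(slope - 2 * pi * 5)), 0.01 * 2 * pi * 5)

  # quadrature identity: phase of sin = phase of cos - pi/2
  ps <- Arg(plvdx:::analytic_signal(sin(2 * pi * 5 * tt)))
  d <- (ph - ps)[core]
  expect_lt(max(abs(atan2(sin(d - pi / 2), cos(d - pi / 2)))), 0.01)

  # amplitude invariance
  p10 <- Arg(plvdx:::analytic_signal(10 * x))
  expect_equal(p10, ph, tolerance = 1e-9)
})

test_that("plv_pair reproduces the limit and hand-computed cases", {
  pp <- make_phase_pair(rep(0.7, 16))
  expect_equal(plv_pair(pp$a, pp$b, 256, 0.1), 1)          # constant diff
  pp0 <- make_phase_pair(2 * pi * (1:16) / 16)
  expect_equal(plv_pair(pp0$a, pp0$b, 256, 0.1), 0,         # roots of unity
               tolerance = 1e-12)
  pph <- make_phase_pair(c(0, 0, 0, pi))
  expect_equal(plv_pair(pph$a, pph$b, 256, 0.1), 0.5)      # |3 - 1| / 4

  expect_error(plv_pair(matrix(0, 10, 3), matrix(0, 10, 2)), "shape")
})

test_that("plv_pair is invariant to a constant global phase offset", {
  set.seed(5)
  a <- matrix(runif(256 * 20, -pi, pi), 256, 20)
  b <- matrix(runif(256 * 20, -pi, pi), 256, 20)
  expect_equal(plv_pair(a + 1.234, b, 256, 0.2),
               plv_pair(a, b, 256, 0.2) , tolerance = 1e-12)
  expect_equal(plv_pair(a, a, 256, 0.2), 1)                # self-PLV
})

test_that("plv_matrix: identical channels give 1, independent stay low", {
  rate <- 256
  rec <- make_sine_recording(freqs = rep(10, 19), duration_s = 30)
  pes <- instantaneous_phase(band_decompose(segment_epochs(rec, 6))$alpha)
  m <- plv_matrix(pes)
  expect_true(all(abs(m[upper.tri(m)] - 1) < 1e-6))
  expect_equal(max(abs(m - t(m))), 0)                      # exact symmetry
  expect_true(all(diag(m) == 1))

  # independent per-epoch phases across channels at N = 200
  set.seed(8)
  cfg <- cohort_config(n_con = 1, n_ci = 1, seed = 8,
                       couplings = default_couplings()[0, ])
  coh <- generate_plv_cohort(cfg, n_epochs = 200)
  v <- as.numeric(coh$table[1, grep("^theta_", names(coh$table))])
  expect_lt(mean(v), 0.12)   # E[PLV] ~ sqrt(pi / (4 N)) = 0.063 at N = 200
})

test_that("plv_matrix respects max_epochs as deterministic first-k", {
  set.seed(9)
  rec <- make_sine_recording(freqs = rep(5, 19), duration_s = 40,
                             noise_sd = 10)
  pes <- instantaneous_phase(band_decompose(segment_epochs(rec, 6))$theta)
  m80 <- plv_matrix(pes, max_epochs = 3)
  expect_equal(attr(m80, "n_epochs_used"), 3)
  pes3 <- pes
  pes3$epochs <- pes$epochs[, , 1:3, drop = FALSE]
  pes3$n_epochs <- 3
  expect_equal(unclass(plv_matrix(pes3)), unclass(m80),
               ignore_attr = TRUE)
})

test_that("channel permutation permutes the PLV matrix accordingly", {
  set.seed(10)
  es <- segment_epochs(make_sine_recording(freqs = rep(6, 19),
                                           duration_s = 15, noise_sd = 20,
                                           seed = 10), 6)
  pes <- instantaneous_phase(band_decompose(es)$theta)
  m <- plv_matrix(pes)
  perm <- sample(19)
  pes_p <- pes
  pes_p$epochs <- pes$epochs[perm, , , drop = FALSE]
  m_p <- plv_matrix(pes_p)
  expect_equal(unclass(m_p), unclass(m)[perm, perm], tolerance = 1e-12,
               ignore_attr = TRUE)
})

test_that("vectorization yields the canonical feature accounting", {
  mats <- lapply(stats::setNames(nm = band_definitions()$name),
                 function(b) {
    m <- diag(1, 19)
    dimnames(m) <- list(canonical_channels(), canonical_channels())
    m
  })
  v <- plv_vectorize(mats)
  expect_length(v, 684)                       # 4 x 171
  expect_length(grep("^theta_", names(v)), 171)
  expect_identical(names(v)[1], "delta_Fp1-Fp2")
  expect_true("theta_T5-T6" %in% names(v))

  toy2 <- matrix(c(1, .5, .5, 1), 2, 2)
  expect_length(plv_vectorize(list(theta = toy2)), 1)       # C(2,2) = 1
  toy5 <- diag(1, 5)
  expect_length(plv_vectorize(list(theta = toy5)), 10)      # C(5,2) = 10
  expect_error(plv_vectorize(list(theta = matrix(0, 2, 3))), "square")
})

test_that("coupled-pair PLV follows the Bessel-ratio law (phase level)", {
  for (kappa in c(0.5, 2, 8)) {
    cfg <- cohort_config(
      n_con = 20, n_ci = 1, seed = 100 + round(10 * kappa),
      couplings = data.frame(band = "theta", ch_a = "Fp1", ch_b = "Fz",
                             plv_con = plv_expected(kappa), plv_ci = 0.5,
                             subject_sd = 0))
    coh <- generate_plv_cohort(cfg, n_epochs = 200)
    con <- coh$table[coh$table$group == "CON", "theta_Fp1-Fz"]
    expect_lt(abs(mean(con) - plv_expected(kappa)), 0.03)
  }
})
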