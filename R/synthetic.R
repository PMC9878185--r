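# ---- circular-statistics primitives --------------------------------------

#' Expected PLV under von Mises phase jitter
#'
#' The mean resultant length of a von Mises distribution with
#' concentration kappa, I1(kappa)/I0(kappa): the expected PLV of a channel
#' pair whose per-epoch phase difference is von Mises distributed.  This
#' Bessel-function ratio is the calibration law of the synthetic
#' generator.
#'
#' @param kappa concentration parameter, >= 0.
#' @return Expected PLV in `[0, 1)`.
#' @export
plv_expected <- function(kappa) {
  stopifnot(all(kappa >= 0))
  # exponentially scaled Bessel ratio is stable for large kappa
  ifelse(kappa == 0, 0,
         besselI(kappa, 1, expon.scaled = TRUE) /
           besselI(kappa, 0, expon.scaled = TRUE))
}

#' Concentration giving a target expected PLV
#'
#' Inverts [plv_expected()]: the standard series/rational approximation
#' (Fisher 1993) refined by Newton steps on the Bessel ratio.
#'
#' @param rho target mean resultant length (expected PLV) in `[0, 1)`.
#' @return kappa such that `plv_expected(kappa) = rho`.
#' @export
kappa_from_plv <- function(rho) {
  stopifnot(all(rho >= 0), all(rho < 1))
  k <- ifelse(rho < 0.53, 2 * rho + rho^3 + 5 * rho^5 / 6,
              ifelse(rho < 0.85, -0.4 + 1.39 * rho + 0.43 / (1 - rho),
                     1 / (rho^3 - 4 * rho^2 + 3 * rho)))
  for (i in 1:4) {                      # Newton: A'(k) = 1 - A^2 - A/k
    a <- plv_expected(k)
    da <- 1 - a^2 - a / pmax(k, 1e-12)
    k <- pmax(k - (a - rho) / pmax(da, 1e-12), 0)
  }
  k
}

#' Draw from the von Mises distribution
#'
#' Best-Fisher (1979) rejection sampler; kappa = 0 degenerates to the
#' uniform circular distribution.  Uses the session RNG.
#'
#' @param n number of draws.
#' @param kappa concentration, >= 0.
#' @param mu mean direction in radians.
#' @return Numeric vector of angles in (-pi, pi].
#' @export
rvonmises <- function(n, kappa, mu = 0) {
  stopifnot(kappa >= 0)
  if (kappa < 1e-8) return(stats::runif(n, -pi, pi))
  a <- 1 + sqrt(1 + 4 * kappa^2)
  b <- (a - sqrt(2 * a)) / (2 * kappa)
  r <- (1 + b^2) / (2 * b)
  out <- numeric(n)
  i <- 1L
  while (i <= n) {
    u <- stats::runif(3)
    z <- cos(pi * u[1])
    f <- (1 + r * z) / (r + z)
    cc <- kappa * (r - f)
    if (cc * (2 - cc) - u[2] > 0 || log(cc / u[2]) + 1 - cc >= 0) {
      out[i] <- sign(u[3] - 0.5) * acos(pmin(pmax(f, -1), 1))
      i <- i + 1L
    }
  }
  ang <- out + mu
  atan2(sin(ang), cos(ang))
}

# internal: 1/f^alpha ("pink") noise via FFT spectral shaping, unit SD
pink_noise <- function(n, exponent = 1) {
  freqs <- seq(0, 1, length.out = floor(n / 2) + 1)
  amp <- c(0, freqs[-1]^(-exponent / 2))
  phase <- stats::runif(length(amp), 0, 2 * pi)
  half <- amp * exp(1i * phase)
  spec <- c(half, Conj(rev(half[2:(n - length(half) + 1)])))
  x <- Re(stats::fft(spec, inverse = TRUE))
  as.numeric(scale(x))
}

# ---- cohort configuration ------------------------------------------------

#' Default implanted phase couplings
#'
#' Five theta-band channel pairs carrying the group contrast: expected
#' PLV 0.35 in the CON group vs 0.65 in the CI group (a gap of 0.3), with
#' between-subject SD 0.2 on the PLV scale.  Under these defaults the
#' analytic Bayes accuracy of the 5-feature contrast is about 0.95.  The
#' pairs are vertex-disjoint within the band, which keeps every
#' non-implanted pair phase-independent by construction.
#'
#' @return data.frame with columns `band`, `ch_a`, `ch_b`, `plv_con`,
#'   `plv_ci`, `subject_sd`.
#' @export
default_couplings <- function() {
  data.frame(band = "theta",
             ch_a = c("T5", "Fp1", "F4", "C4", "F3"),
             ch_b = c("T6", "Pz", "F7", "P3", "F8"),
             plv_con = 0.35, plv_ci = 0.65, subject_sd = 0.2,
             stringsAsFactors = FALSE)
}

#' Synthetic cohort configuration
#'
#' Bundles the study conditions emulated by the generators: group sizes
#' (55 CON / 76 CI), 20-minute 19-channel recordings at 256 Hz cut into
#' 6-s epochs (200 per subject), implanted per-band phase couplings, 1/f
#' background noise, band oscillation amplitudes, and per-feature clinical
#' distributions.
#'
#' @param n_con,n_ci group sizes.
#' @param duration_s recording length in seconds (default 1200).
#' @param rate_hz sampling rate (default 256).
#' @param epoch_length_s epoch length in seconds (default 6).
#' @param couplings coupling table as from [default_couplings()].
#' @param band_amplitudes named amplitudes (uV) of the four band
#'   oscillations.
#' @param noise list with `exponent` (1/f power-law exponent) and `sd`
#'   (broadband noise SD in uV).
#' @param clinical_spec per-feature group distributions, as from
#'   [table2_clinical_spec()].
#' @param seed integer master seed.
#' @return A `cohort_config` list.
#' @export
cohort_config <- function(n_con = 55, n_ci = 76, duration_s = 1200,
                          rate_hz = 256, epoch_length_s = 6,
                          couplings = default_couplings(),
                          band_amplitudes = c(delta = 20, theta = 15,
                                              alpha = 20, beta = 10),
                          noise = list(exponent = 1, sd = 5),
                          clinical_spec = table2_clinical_spec(),
                          seed = 1) {
  stopifnot(n_con > 0, n_ci > 0, duration_s > 0, rate_hz > 0)
  bad <- setdiff(c(couplings$ch_a, couplings$ch_b), canonical_channels())
  if (length(bad)) stop("coupling references unknown channel(s): ",
                        paste(unique(bad), collapse = ", "))
  if (any(couplings$ch_a == couplings$ch_b))
    stop("coupling channels must be distinct")
  # the phase model supports one coupling per channel per band: a channel
  # in two couplings of a band would chain phases and change expectations
  for (band in unique(couplings$band)) {
    cp <- couplings[couplings$band == band, ]
    ch <- c(cp$ch_a, cp$ch_b)
    if (anyDuplicated(ch))
      stop("couplings within band '", band,
           "' must use vertex-disjoint channel pairs")
  }
  structure(list(n_con = n_con, n_ci = n_ci, duration_s = duration_s,
                 rate_hz = rate_hz, epoch_length_s = epoch_length_s,
                 couplings = couplings, band_amplitudes = band_amplitudes,
                 noise = noise, clinical_spec = clinical_spec, seed = seed),
            class = "cohort_config")
}

# internal: resolve a subject's coupling concentrations.  The group-level
# expected PLV gets optional between-subject jitter on the PLV scale
# (truncated to [0.02, 0.98]) and is inverted to a concentration.
subject_kappas <- function(couplings, group) {
  rho <- if (group == "CON") couplings$plv_con else couplings$plv_ci
  sd <- couplings$subject_sd %||% 0
  if (any(sd > 0))
    rho <- pmin(pmax(stats::rnorm(length(rho), rho, sd), 0.02), 0.98)
  kappa_from_plv(rho)
}

# ---- EEG waveform generator ----------------------------------------------

#' Generate one synthetic EEG recording
#'
#' Each channel is a sum over the four bands of a band-centred oscillation
#' plus 1/f background noise.  Oscillation phases are redrawn uniformly
#' per 6-s epoch and per channel; for each implanted coupling the second
#' channel's phase in that band equals the first channel's plus one von
#' Mises(kappa) draw per epoch, so the across-epoch PLV estimator has
#' expectation I1(kappa)/I0(kappa) exactly.  All other pairs are
#' phase-independent by construction.
#'
#' @param cfg a [cohort_config()].
#' @param subject_index integer used (with `cfg$seed`) to seed this
#'   subject's draw.
#' @param group `"CON"` or `"CI"`, selecting the coupling strengths.
#' @return An [eeg_recording].
#' @export
generate_eeg <- function(cfg, subject_index = 1, group = c("CON", "CI")) {
  stopifnot(inherits(cfg, "cohort_config"))
  group <- match.arg(group)
  chans <- canonical_channels()
  rate <- cfg$rate_hz
  n <- round(cfg$duration_s * rate)
  L <- round(cfg$epoch_length_s * rate)
  n_ep <- ceiling(n / L)
  bands <- band_definitions()
  tt <- (seq_len(n) - 1) / rate
  epoch_of <- pmin((seq_len(n) - 1) %/% L + 1, n_ep)

  with_seed(cfg$seed * 1000L + subject_index, {
    x <- matrix(0, 19, n, dimnames = list(chans, NULL))
    for (b in seq_len(nrow(bands))) {
      f_c <- (bands$low_hz[b] + bands$high_hz[b]) / 2
      amp <- cfg$band_amplitudes[[bands$name[b]]]
      phi <- matrix(stats::runif(19 * n_ep, -pi, pi), 19, n_ep)
      cp <- cfg$couplings[cfg$couplings$band == bands$name[b], ,
                          drop = FALSE]
      if (nrow(cp)) {
        kap <- subject_kappas(cp, group)
        for (j in seq_len(nrow(cp))) {
          ia <- match(cp$ch_a[j], chans); ib <- match(cp$ch_b[j], chans)
          phi[ib, ] <- phi[ia, ] + rvonmises(n_ep, kap[j])
        }
      }
      carrier <- 2 * pi * f_c * tt
      for (ch in 1:19)
        x[ch, ] <- x[ch, ] + amp * cos(carrier + phi[ch, epoch_of])
    }
    for (ch in 1:19)
      x[ch, ] <- x[ch, ] + cfg$noise$sd * pink_noise(n, cfg$noise$exponent)
  })
  eeg_recording(x, rate, subject_id = sprintf("%s%03d", group,
                                              subject_index))
}

# ---- phase-level cohort generator ----------------------------------------

#' Generate a cohort of PLV feature vectors from the phase model
#'
#' Draws the per-epoch phase model directly -- per channel and epoch a
#' uniform phase, with implanted couplings adding von Mises jitter to a
#' shared phase -- and computes the 4 x 171 = 684 PLV features from those
#' phases, without synthesising waveforms.  This is the estimator the
#' waveform path converges to (the full pipeline is validated against the
#' same Bessel-ratio law), and it makes feature-scale experiments cheap.
#'
#' @param cfg a [cohort_config()]; `n_epochs` below overrides the epoch
#'   count implied by `duration_s`.
#' @param n_epochs epochs per subject (default from `cfg`).
#' @return List: `table` (a `subject_table` of 684 PLV features with
#'   groups), `implanted` (canonical names of the coupled features),
#'   `config`.
#' @export
generate_plv_cohort <- function(cfg = cohort_config(),
                                n_epochs = NULL) {
  stopifnot(inherits(cfg, "cohort_config"))
  if (is.null(n_epochs))
    n_epochs <- floor(cfg$duration_s / cfg$epoch_length_s)
  chans <- canonical_channels()
  bands <- band_definitions()$name
  groups <- c(rep("CON", cfg$n_con), rep("CI", cfg$n_ci))
  ids <- sprintf("S%03d", seq_along(groups))
  rows <- vector("list", length(groups))
  with_seed(cfg$seed, {
    for (s in seq_along(groups)) {
      mats <- vector("list", length(bands))
      names(mats) <- bands
      for (band in bands) {
        phi <- matrix(stats::runif(19 * n_epochs, -pi, pi), 19, n_epochs)
        cp <- cfg$couplings[cfg$couplings$band == band, , drop = FALSE]
        if (nrow(cp)) {
          kap <- subject_kappas(cp, groups[s])
          for (j in seq_len(nrow(cp))) {
            ia <- match(cp$ch_a[j], chans); ib <- match(cp$ch_b[j], chans)
            phi[ib, ] <- phi[ia, ] + rvonmises(n_epochs, kap[j])
          }
        }
        z <- exp(1i * phi)
        p <- Mod(z %*% Conj(t(z))) / n_epochs
        diag(p) <- 1
        dimnames(p) <- list(chans, chans)
        mats[[band]] <- p
      }
      rows[[s]] <- plv_vectorize(mats)
    }
  })
  plv <- do.call(rbind, rows)
  rownames(plv) <- ids
  tab <- assemble_table(plv = plv, view = "plv",
                        labels = stats::setNames(groups, ids))
  implanted <- vapply(seq_len(nrow(cfg$couplings)), function(j) {
    ia <- match(cfg$couplings$ch_a[j], chans)
    ib <- match(cfg$couplings$ch_b[j], chans)
    ij <- sort(c(ia, ib))
    paste0(cfg$couplings$band[j], "_", chans[ij[1]], "-", chans[ij[2]])
  }, "")
  list(table = tab, implanted = implanted, config = cfg)
}

# ---- clinical table generator --------------------------------------------

#' Clinical feature distributions of the reference cohort
#'
#' Per-group category frequencies and continuous-feature moments used as
#' generator defaults: CON n = 55, CI n = 76.  Age and age at first onset
#' are truncated normals; disease duration is derived as age minus onset
#' so the record stays internally consistent.
#'
#' @return List with `continuous` (per-feature per-group mean/sd) and
#'   `categorical` (per-feature per-group probabilities).
#' @export
table2_clinical_spec <- function() {
  cat2 <- function(con_counts, ci_counts, levels) {
    list(levels = levels,
         CON = con_counts / sum(con_counts),
         CI = ci_counts / sum(ci_counts))
  }
  yn <- function(con_y, n_con, ci_y, n_ci)
    cat2(c(n_con - con_y, con_y), c(n_ci - ci_y, ci_y), c("N", "Y"))
  list(
    continuous = list(
      age_y = list(CON = c(26.38, 10.49), CI = c(31.34, 13.93),
                   lower = 12, upper = 60),
      age_first_onset_y = list(CON = c(18.76, 11.02), CI = c(20.71, 14.74),
                               lower = 0, upper = 60)),
    categorical = list(
      gender = cat2(c(31, 24), c(37, 39), c("male", "female")),
      family_history = yn(2, 55, 5, 76),
      head_surgery_trauma = yn(6, 55, 17, 76),
      cns_infection = yn(8, 55, 18, 76),
      perinatal_injury = yn(4, 55, 8, 76),
      tle = yn(27, 55, 48, 76),
      mri_abnormal = yn(28, 55, 51, 76),
      hippocampal_atrophy_sclerosis = yn(14, 55, 37, 76),
      seizure_type = cat2(c(13, 7, 35), c(21, 9, 46),
                          c("generalized", "focal", "both")),
      status_epilepticus = yn(4, 55, 15, 76),
      gtcs = yn(45, 55, 67, 76),
      seizure_frequency = cat2(c(17, 15, 23), c(12, 11, 53),
                               c("rare", "occasional", "frequent")),
      asm_class_ge2 = yn(18, 55, 41, 76),
      vpa = yn(17, 55, 40, 76),
      pht = yn(1, 55, 2, 76),
      tpm = yn(3, 55, 4, 76),
      aura = yn(22, 55, 24, 76),
      anxiety = cat2(c(14, 13, 25, 3), c(12, 21, 35, 8),
                     c("none", "possible", "definitely",
                       "definitely_obvious")),
      depression = cat2(c(23, 31, 1), c(25, 48, 3),
                        c("none", "possible", "definitely")),
      education = cat2(c(1, 11, 15, 28), c(23, 18, 19, 16),
                       c("<=6y", "7-9y", "10-12y", ">=13y"))))
}

# internal: truncated normal by rejection
rtruncnorm <- function(n, mean, sd, lower, upper) {
  out <- numeric(n)
  need <- seq_len(n)
  while (length(need)) {
    draw <- stats::rnorm(length(need), mean, sd)
    ok <- draw >= lower & draw <= upper
    out[need[ok]] <- draw[ok]
    need <- need[!ok]
  }
  out
}

#' Generate a synthetic clinical table
#'
#' Draws per-group category frequencies and continuous features from the
#' configured distributions (see [table2_clinical_spec()]); disease
#' duration is age minus age at first onset, keeping records internally
#' consistent.  Output is in the string form accepted by
#' [encode_clinical()].
#'
#' @param cfg a [cohort_config()].
#' @return data.frame with `subject_id`, `group` and the 23 clinical
#'   features.
#' @export
generate_clinical <- function(cfg = cohort_config()) {
  stopifnot(inherits(cfg, "cohort_config"))
  spec <- cfg$clinical_spec
  for (f in names(spec$categorical)) {
    pr <- spec$categorical[[f]]
    for (g in c("CON", "CI"))
      if (abs(sum(pr[[g]]) - 1) > 1e-8)
        stop("categorical probabilities for '", f, "' (", g,
             ") do not sum to 1")
  }
  groups <- c(rep("CON", cfg$n_con), rep("CI", cfg$n_ci))
  n <- length(groups)
  out <- data.frame(subject_id = sprintf("S%03d", seq_len(n)),
                    group = groups, stringsAsFactors = FALSE)
  with_seed(cfg$seed + 1L, {
    for (g in c("CON", "CI")) {
      sel <- out$group == g
      cs <- spec$continuous
      age <- rtruncnorm(sum(sel), cs$age_y[[g]][1], cs$age_y[[g]][2],
                        cs$age_y$lower, cs$age_y$upper)
      on <- cs$age_first_onset_y
      onset <- numeric(sum(sel))
      for (i in seq_along(onset))
        onset[i] <- rtruncnorm(1, on[[g]][1], on[[g]][2], on$lower, age[i])
      out$age_y[sel] <- round(age, 1)
      out$age_first_onset_y[sel] <- round(onset, 1)
      out$years_since_onset[sel] <- round(age - onset, 1)
      for (f in names(spec$categorical)) {
        pr <- spec$categorical[[f]]
        out[[f]][sel] <- sample(pr$levels, sum(sel), replace = TRUE,
                                prob = pr[[g]])
      }
    }
  })
  out
}
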