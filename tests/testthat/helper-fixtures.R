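# Fixtures are built in code: no binary data ships with the package.

# simple phase unwrapping for oracle checks
unwrap_phase <- function(p) {
  d <- diff(p)
  d <- d - 2 * pi * round(d / (2 * pi))
  cumsum(c(p[1], d))
}

# a recording whose channels are sinusoids (+ optional noise), canonical
# montage, default 256 Hz
make_sine_recording <- function(freqs = rep(10, 19), duration_s = 10,
                                rate = 256, amp = 50, noise_sd = 0,
                                phases = rep(0, 19), seed = 1) {
  tt <- (seq_len(duration_s * rate) - 1) / rate
  x <- t(vapply(seq_len(19), function(ch)
    amp * cos(2 * pi * freqs[ch] * tt + phases[ch]), numeric(length(tt))))
  if (noise_sd > 0) {
    set.seed(seed)
    x <- x + matrix(rnorm(length(x), 0, noise_sd), nrow = 19)
  }
  eeg_recording(x, rate, subject_id = "fix")
}

# phase matrices (samples x epochs) with a chosen per-epoch phase offset
make_phase_pair <- function(offsets, n_samples = 256) {
  list(a = matrix(0, n_samples, length(offsets)),
       b = matrix(rep(-offsets, each = n_samples), n_samples,
                  length(offsets)))
}

# a small valid clinical table in string form
make_clinical_df <- function(n = 6, seed = 1) {
  cfg <- cohort_config(n_con = ceiling(n / 2), n_ci = floor(n / 2),
                       seed = seed)
  generate_clinical(cfg)
}

# deterministic linearly separable two-feature table
make_separable_table <- function(n_per_class = 20, gap = 4, seed = 1) {
  set.seed(seed)
  x <- rbind(matrix(rnorm(n_per_class * 2), ncol = 2),
             matrix(rnorm(n_per_class * 2) + gap, ncol = 2))
  colnames(x) <- c("f1", "f2")
  y <- factor(rep(c("CON", "CI"), each = n_per_class),
              levels = c("CON", "CI"))
  list(x = x, y = y)
}
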