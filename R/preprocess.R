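#' Frequency-band definitions
#'
#' The four classical EEG bands used for PLV extraction: delta 1-4 Hz,
#' theta 4-7 Hz, alpha 8-13 Hz, beta 14-30 Hz.  The small gaps in this
#' table (7-8 Hz unassigned, 0.5-1 Hz broadband-filtered but in no band)
#' are deliberate defaults; pass a modified data frame to change them.
#'
#' @return data.frame with columns `name`, `low_hz`, `high_hz`.
#' @export
band_definitions <- function() {
  data.frame(name = c("delta", "theta", "alpha", "beta"),
             low_hz = c(1, 4, 8, 14),
             high_hz = c(4, 7, 13, 30),
             stringsAsFactors = FALSE)
}

# internal: design the zero-phase band-pass used everywhere.
# 4th-order Butterworth, applied forward-backward with signal::filtfilt,
# so the effective magnitude response is |H|^2 and the phase delay is zero
# (phase estimation downstream must not be biased by filter delay).
design_bandpass <- function(low_hz, high_hz, rate) {
  nyq <- rate / 2
  if (!(low_hz > 0 && low_hz < high_hz && high_hz < nyq))
    stop("invalid band edges: need 0 < low < high < Nyquist (", nyq, " Hz)")
  signal::butter(4, c(low_hz, high_hz) / nyq, type = "pass")
}

# internal: per-channel zero-phase filtering of a channels x samples matrix
filter_matrix <- function(x, filt) {
  out <- x
  for (ch in seq_len(nrow(x)))
    out[ch, ] <- signal::filtfilt(filt, x[ch, ])
  out
}

#' Broadband filter a recording
#'
#' Zero-phase (forward-backward) 4th-order Butterworth band-pass applied
#' per channel to the continuous recording, by default 0.5-30 Hz.
#'
#' @param rec an [eeg_recording].
#' @param low_hz,high_hz band edges in Hz; `high_hz` must be below Nyquist.
#' @return Filtered [eeg_recording] of identical shape.
#' @export
broadband_filter <- function(rec, low_hz = 0.5, high_hz = 30) {
  stopifnot(inherits(rec, "eeg_recording"))
  filt <- design_bandpass(low_hz, high_hz, rec$sampling_rate_hz)
  rec$data <- filter_matrix(rec$data, filt)
  rec
}

#' Reject high-amplitude epochs
#'
#' Removes every epoch whose peak absolute amplitude on any channel
#' exceeds the threshold.  A simple cleaning stage for residual artifacts;
#' the default threshold used in practice is 100 uV.
#'
#' @param es an `epoch_set`.
#' @param abs_amp_threshold_uv positive amplitude threshold in microvolts.
#' @return The `epoch_set` with offending epochs removed, order preserved.
#' @export
reject_epochs <- function(es, abs_amp_threshold_uv) {
  stopifnot(inherits(es, "epoch_set"))
  if (!is.numeric(abs_amp_threshold_uv) || abs_amp_threshold_uv <= 0)
    stop("threshold must be positive")
  peak <- apply(abs(es$epochs), 3, max)
  keep <- which(peak <= abs_amp_threshold_uv)
  if (length(keep) == 0)
    stop("all epochs rejected at threshold ", abs_amp_threshold_uv,
         " uV; review the threshold")
  replace_epochs(es, es$epochs[, , keep, drop = FALSE])
}

#' Decompose epochs into narrow frequency bands
#'
#' Applies the zero-phase band-pass of each band to every epoch of every
#' channel.  Narrowband signals are a precondition for meaningful
#' Hilbert-transform instantaneous phase.
#'
#' @param es an `epoch_set`.
#' @param bands band table as from [band_definitions()].
#' @return Named list of `band_epoch_set` objects (one per band), each an
#'   `epoch_set` with an extra `band` field.
#' @export
band_decompose <- function(es, bands = band_definitions()) {
  stopifnot(inherits(es, "epoch_set"))
  out <- vector("list", nrow(bands))
  names(out) <- bands$name
  dm <- dim(es$epochs)
  for (b in seq_len(nrow(bands))) {
    filt <- design_bandpass(bands$low_hz[b], bands$high_hz[b],
                            es$sampling_rate_hz)
    a <- es$epochs
    for (k in seq_len(dm[3]))
      a[, , k] <- filter_matrix(es$epochs[, , k], filt)
    bes <- replace_epochs(es, a)
    bes$band <- bands[b, ]
    class(bes) <- c("band_epoch_set", "epoch_set")
    out[[b]] <- bes
  }
  out
}
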