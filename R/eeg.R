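#' Canonical 10-20 channel order
#'
#' The fixed 19-lead scalp montage used throughout the package.  Every
#' [eeg_recording] is mapped onto these labels in exactly this order; the
#' order also fixes the channel-pair order of PLV feature vectors, so it is
#' part of the public contract.
#'
#' @return Character vector of 19 channel labels.
#' @export
canonical_channels <- function() {
  c("Fp1", "Fp2", "Fz", "Cz", "Pz", "C3", "C4", "T3", "T4", "T5", "T6",
    "F3", "F4", "F7", "F8", "O1", "O2", "P3", "P4")
}

#' Construct an EEG recording object
#'
#' A light container for a fixed-montage multichannel signal.  Rows of
#' `data` are channels in the canonical 10-20 order (see
#' [canonical_channels()]), values are microvolts.
#'
#' @param data numeric matrix, channels x samples, microvolts.
#' @param sampling_rate_hz positive sampling rate (nominally 256).
#' @param subject_id opaque subject identifier.
#' @param channel_labels labels for the rows of `data`; must be exactly the
#'   canonical 19 labels in canonical order.
#' @return An object of class `eeg_recording` with fields `subject_id`,
#'   `channel_labels`, `sampling_rate_hz`, `data` and derived `duration_s`.
#' @export
eeg_recording <- function(data, sampling_rate_hz, subject_id = "anon",
                          channel_labels = canonical_channels()) {
  if (!is.matrix(data) || !is.numeric(data))
    stop("`data` must be a numeric channels x samples matrix")
  if (length(channel_labels) != nrow(data))
    stop("channel_labels length must equal nrow(data)")
  if (!identical(channel_labels, canonical_channels()))
    stop("channels must be the canonical 19 labels in canonical order")
  if (!is.numeric(sampling_rate_hz) || length(sampling_rate_hz) != 1 ||
      sampling_rate_hz <= 0)
    stop("sampling_rate_hz must be a positive scalar")
  rownames(data) <- channel_labels
  structure(
    list(subject_id = as.character(subject_id),
         channel_labels = channel_labels,
         sampling_rate_hz = sampling_rate_hz,
         data = data,
         duration_s = ncol(data) / sampling_rate_hz),
    class = "eeg_recording")
}

#' @export
print.eeg_recording <- function(x, ...) {
  cat(sprintf("<eeg_recording> subject %s: %d channels, %.1f s at %g Hz\n",
              x$subject_id, nrow(x$data), x$duration_s, x$sampling_rate_hz))
  invisible(x)
}

#' Cut a recording into fixed-length non-overlapping epochs
#'
#' Epochs are contiguous, non-overlapping and in temporal order; any
#' trailing remainder shorter than one epoch is discarded.  A 20-minute
#' recording at the default 6-s epoch length yields 200 epochs.
#'
#' @param rec an [eeg_recording].
#' @param epoch_length_s epoch length in seconds (default 6).
#' @return An object of class `epoch_set`: list with `subject_id`,
#'   `sampling_rate_hz`, `epoch_length_s`, `epochs` (channels x samples x
#'   epochs array) and `n_epochs`.
#' @export
segment_epochs <- function(rec, epoch_length_s = 6) {
  stopifnot(inherits(rec, "eeg_recording"))
  L <- round(epoch_length_s * rec$sampling_rate_hz)
  if (L < 1 || ncol(rec$data) < L)
    stop("recording shorter than one epoch (", epoch_length_s, " s)")
  n_epochs <- ncol(rec$data) %/% L
  a <- array(rec$data[, seq_len(n_epochs * L), drop = FALSE],
             dim = c(nrow(rec$data), L, n_epochs),
             dimnames = list(rec$channel_labels, NULL, NULL))
  structure(
    list(subject_id = rec$subject_id,
         sampling_rate_hz = rec$sampling_rate_hz,
         epoch_length_s = epoch_length_s,
         epochs = a,
         n_epochs = n_epochs),
    class = "epoch_set")
}

#' @export
print.epoch_set <- function(x, ...) {
  cat(sprintf("<epoch_set> subject %s: %d epochs of %g s (%d ch) at %g Hz\n",
              x$subject_id, x$n_epochs, x$epoch_length_s,
              dim(x$epochs)[1], x$sampling_rate_hz))
  invisible(x)
}

# internal: epoch_set with same metadata but new epoch array
replace_epochs <- function(es, epochs) {
  es$epochs <- epochs
  es$n_epochs <- dim(epochs)[3]
  es
}
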