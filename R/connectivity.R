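# internal: analytic signal by the FFT method (Marple 1999).  The angle of
# the analytic signal is the instantaneous phase; valid for narrowband x.
analytic_signal <- function(x) {
  n <- length(x)
  X <- stats::fft(x)
  h <- numeric(n)
  if (n %% 2 == 0) {
    h[1] <- 1; h[n / 2 + 1] <- 1; h[2:(n / 2)] <- 2
  } else {
    h[1] <- 1; h[2:((n + 1) / 2)] <- 2
  }
  stats::fft(X * h, inverse = TRUE) / n
}

#' Instantaneous phase of narrowband epochs
#'
#' Computes the Hilbert-transform analytic signal per channel per epoch and
#' returns its angle, wrapped to (-pi, pi].
#'
#' @param bes a `band_epoch_set` (see [band_decompose()]).
#' @return A `phase_epoch_set`: same shape as the input, `epochs` holding
#'   phases in radians.
#' @export
instantaneous_phase <- function(bes) {
  stopifnot(inherits(bes, "epoch_set"))
  ph <- bes$epochs
  dm <- dim(ph)
  for (k in seq_len(dm[3]))
    for (ch in seq_len(dm[1]))
      ph[ch, , k] <- Arg(analytic_signal(bes$epochs[ch, , k]))
  out <- replace_epochs(bes, ph)
  class(out) <- c("phase_epoch_set", class(bes))
  out
}

#' Phase-locking value between two phase series
#'
#' Implements, per time point t, PLV(t) = (1/N) |sum_n exp(i dphi(t, n))|
#' where dphi(t, n) is the phase difference at time t in epoch n and N the
#' number of epochs, then averages PLV(t) over the epoch interior
#' (`edge_trim_s` seconds excluded at each end to avoid Hilbert edge
#' distortion).  PLV = 1 iff the phase difference is constant across
#' epochs at every retained t; PLV = 0 when phase differences are
#' uniformly spread around the circle.
#'
#' @param phase_a,phase_b numeric matrices (samples x epochs) of phases in
#'   radians, identical shapes.
#' @param sampling_rate_hz sampling rate used to convert `edge_trim_s` to
#'   samples.
#' @param edge_trim_s seconds trimmed from each epoch end (default 0.5).
#' @return Scalar PLV in `[0, 1]`.
#' @export
plv_pair <- function(phase_a, phase_b, sampling_rate_hz = 256,
                     edge_trim_s = 0.5) {
  phase_a <- as.matrix(phase_a); phase_b <- as.matrix(phase_b)
  if (!identical(dim(phase_a), dim(phase_b)))
    stop("phase series shapes differ")
  z <- exp(1i * (phase_a - phase_b))
  plv_t <- Mod(rowMeans(z))
  idx <- interior_index(nrow(phase_a), sampling_rate_hz, edge_trim_s)
  mean(plv_t[idx])
}

# internal: interior sample index after trimming both epoch ends
interior_index <- function(n_samples, rate, edge_trim_s) {
  trim <- floor(edge_trim_s * rate)
  if (2 * trim >= n_samples)
    stop("edge_trim_s leaves no interior samples")
  (trim + 1):(n_samples - trim)
}

#' PLV connectivity matrix over all channel pairs
#'
#' Evaluates [plv_pair()] for every unordered channel pair of a
#' `phase_epoch_set` (171 pairs for the 19-lead montage).  The diagonal is
#' fixed at 1 (self-synchrony) and never exported as a feature.
#'
#' @param pes a `phase_epoch_set`.
#' @param edge_trim_s seconds trimmed from each epoch end (default 0.5).
#' @param max_epochs optional cap: use only the first `max_epochs` epochs
#'   (deterministic first-k selection); `NULL` (default) uses all.
#' @return A `plv_matrix`: symmetric channels x channels matrix with unit
#'   diagonal, with attributes `subject_id`, `band`, `n_epochs_used`.
#' @export
plv_matrix <- function(pes, edge_trim_s = 0.5, max_epochs = NULL) {
  stopifnot(inherits(pes, "phase_epoch_set"))
  ph <- pes$epochs
  if (!is.null(max_epochs)) {
    if (max_epochs < 1) stop("max_epochs must be >= 1")
    k <- min(max_epochs, dim(ph)[3])
    ph <- ph[, , seq_len(k), drop = FALSE]
  }
  dm <- dim(ph)
  idx <- interior_index(dm[2], pes$sampling_rate_hz, edge_trim_s)
  z <- exp(1i * ph)
  labels <- dimnames(pes$epochs)[[1]]
  m <- diag(1, dm[1])
  dimnames(m) <- list(labels, labels)
  for (a in seq_len(dm[1] - 1)) {
    za <- matrix(z[a, , ], dm[2], dm[3])
    for (b in (a + 1):dm[1]) {
      zb <- matrix(z[b, , ], dm[2], dm[3])
      plv_t <- Mod(rowMeans(za * Conj(zb)))
      m[a, b] <- m[b, a] <- mean(plv_t[idx])
    }
  }
  structure(m, class = c("plv_matrix", "matrix"),
            subject_id = pes$subject_id, band = pes$band$name,
            n_epochs_used = dm[3])
}

#' @export
print.plv_matrix <- function(x, ...) {
  cat(sprintf("<plv_matrix> subject %s, band %s, %d x %d, N = %d epochs\n",
              attr(x, "subject_id"), attr(x, "band"), nrow(x), ncol(x),
              attr(x, "n_epochs_used")))
  print(unclass(x)[seq_len(min(5, nrow(x))), seq_len(min(5, ncol(x)))], ...)
  invisible(x)
}

#' Vectorize per-band PLV matrices into a named feature vector
#'
#' Flattens the upper triangle (excluding the diagonal) of each band's
#' matrix in canonical pair order and concatenates bands.  For the 19-lead
#' montage this yields 171 features per band and 684 in total, named
#' `"<band>_<chA>-<chB>"` (e.g. `"theta_T5-T6"`).
#'
#' @param band_matrices named list of square PLV matrices (names are band
#'   names); all matrices must share one channel set.
#' @return Named numeric vector of length `n_bands * choose(n_ch, 2)`.
#' @export
plv_vectorize <- function(band_matrices) {
  stopifnot(is.list(band_matrices), length(band_matrices) >= 1,
            !is.null(names(band_matrices)))
  out <- numeric(0)
  for (band in names(band_matrices)) {
    m <- band_matrices[[band]]
    if (!is.matrix(m) || nrow(m) != ncol(m))
      stop("band ", band, ": PLV matrix must be square")
    labels <- rownames(m)
    if (is.null(labels)) labels <- paste0("ch", seq_len(nrow(m)))
    v <- numeric(0)
    nm <- character(0)
    for (a in seq_len(nrow(m) - 1)) {
      for (b in (a + 1):nrow(m)) {
        v <- c(v, m[a, b])
        nm <- c(nm, paste0(band, "_", labels[a], "-", labels[b]))
      }
    }
    out <- c(out, stats::setNames(v, nm))
  }
  out
}

#' Full per-subject PLV feature extraction
#'
#' Convenience wrapper running the whole connectivity stage on one
#' recording: broadband filter, epoching, optional amplitude-based epoch
#' rejection, band decomposition, Hilbert phase, PLV matrices, and
#' vectorization.
#'
#' @param rec an [eeg_recording].
#' @param bands band table as from [band_definitions()].
#' @param epoch_length_s epoch length in seconds.
#' @param broadband low/high edges of the initial broadband filter.
#' @param reject_uv amplitude-rejection threshold in uV, or `NULL` (default)
#'   to skip rejection.
#' @param edge_trim_s per-epoch edge trim for phase statistics.
#' @param max_epochs optional first-k epoch cap passed to [plv_matrix()].
#' @return List with `matrices` (named list of `plv_matrix`) and `vector`
#'   (named feature vector, 684-long for the 19-channel montage).
#' @export
extract_plv_features <- function(rec, bands = band_definitions(),
                                 epoch_length_s = 6, broadband = c(0.5, 30),
                                 reject_uv = NULL, edge_trim_s = 0.5,
                                 max_epochs = NULL) {
  rec <- broadband_filter(rec, broadband[1], broadband[2])
  es <- segment_epochs(rec, epoch_length_s)
  if (!is.null(reject_uv)) es <- reject_epochs(es, reject_uv)
  bsets <- band_decompose(es, bands)
  mats <- lapply(bsets, function(bes)
    plv_matrix(instantaneous_phase(bes), edge_trim_s = edge_trim_s,
               max_epochs = max_epochs))
  list(matrices = mats, vector = plv_vectorize(mats))
}
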