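#' Default channel-label alias table
#'
#' EDF label dialects vary by vendor: labels may carry an "EEG " prefix,
#' reference suffixes ("-A1", "-REF", ...), or use the modern 10-10 names
#' for the temporal leads (T7/T8/P7/P8 for T3/T4/T5/T6).  The alias table
#' maps, case-insensitively, a cleaned-up label to its canonical name.
#'
#' @return Named character vector: names are alias labels (lower case),
#'   values canonical labels.
#' @export
default_montage_map <- function() {
  canon <- canonical_channels()
  map <- stats::setNames(canon, tolower(canon))
  c(map, c(t7 = "T3", t8 = "T4", p7 = "T5", p8 = "T6"))
}

# internal: strip vendor decoration and resolve a raw EDF label to its
# canonical channel name, or NA if it is not one of the 19 leads
resolve_label <- function(raw, montage_map) {
  lab <- trimws(raw)
  lab <- sub("^EEG[ _]*", "", lab, ignore.case = TRUE)
  lab <- sub("[-_ ](A1|A2|REF|LE|AVG|M1|M2)$", "", lab, ignore.case = TRUE)
  hit <- montage_map[tolower(lab)]
  ifelse(is.na(hit), NA_character_, unname(hit))
}

# internal: fixed-width ASCII field helpers for the EDF header
edf_field <- function(con, n) trimws(rawToChar(readBin(con, "raw", n)))
edf_pad <- function(x, n) {
  s <- formatC(as.character(x), width = -n)
  if (nchar(s) > n) stop("EDF header field too wide: ", x)
  s
}

#' Read an EDF/EDF+ file into the canonical 19-channel montage
#'
#' Parses the EDF header and 16-bit data records, converts each retained
#' signal to physical units (microvolts), resolves vendor label dialects
#' through `montage_map`, drops reference (A1/A2) and any other
#' non-montage channels, and reorders the result into the canonical
#' channel order.
#'
#' @param path path to an EDF/EDF+ file.
#' @param montage_map label alias table as from [default_montage_map()].
#' @return An [eeg_recording].
#' @export
read_edf <- function(path, montage_map = default_montage_map()) {
  con <- file(path, "rb")
  on.exit(close(con))

  version <- edf_field(con, 8)
  if (!startsWith(version, "0"))
    stop("not an EDF file (bad version field): ", path)
  patient <- edf_field(con, 80)
  edf_field(con, 80)                    # recording id
  edf_field(con, 8); edf_field(con, 8)  # start date/time
  edf_field(con, 8)                     # header bytes
  edf_field(con, 44)                    # reserved
  n_records <- as.integer(edf_field(con, 8))
  record_dur <- as.numeric(edf_field(con, 8))
  ns <- as.integer(edf_field(con, 4))
  if (is.na(ns) || ns < 1) stop("invalid EDF: no signals")

  labels    <- vapply(seq_len(ns), function(i) edf_field(con, 16), "")
  for (i in seq_len(ns)) edf_field(con, 80)          # transducer
  phys_dim  <- vapply(seq_len(ns), function(i) edf_field(con, 8), "")
  phys_min  <- as.numeric(vapply(seq_len(ns), function(i) edf_field(con, 8), ""))
  phys_max  <- as.numeric(vapply(seq_len(ns), function(i) edf_field(con, 8), ""))
  dig_min   <- as.numeric(vapply(seq_len(ns), function(i) edf_field(con, 8), ""))
  dig_max   <- as.numeric(vapply(seq_len(ns), function(i) edf_field(con, 8), ""))
  for (i in seq_len(ns)) edf_field(con, 80)          # prefiltering
  spr       <- as.integer(vapply(seq_len(ns), function(i) edf_field(con, 8), ""))
  for (i in seq_len(ns)) edf_field(con, 32)          # reserved

  canon <- resolve_label(labels, montage_map)
  keep <- which(!is.na(canon))
  missing <- setdiff(canonical_channels(), canon[keep])
  if (length(missing))
    stop("EDF is missing canonical channel(s): ",
         paste(missing, collapse = ", "))
  rates <- spr[keep] / record_dur
  if (length(unique(rates)) != 1)
    stop("inconsistent sampling rates across retained channels")
  rate <- rates[1]

  # unit scale to microvolts from the physical-dimension field
  unit_scale <- function(dim) {
    switch(tolower(dim), "uv" = 1, "µv" = 1, "mv" = 1e3, "v" = 1e6, 1)
  }

  sig <- vector("list", ns)
  for (i in seq_len(ns)) sig[[i]] <- numeric(n_records * spr[i])
  for (r in seq_len(n_records)) {
    for (i in seq_len(ns)) {
      v <- readBin(con, "integer", n = spr[i], size = 2,
                   signed = TRUE, endian = "little")
      sig[[i]][((r - 1) * spr[i] + 1):(r * spr[i])] <- v
    }
  }

  ord <- keep[match(canonical_channels(), canon[keep])]
  data <- matrix(0, nrow = 19, ncol = n_records * spr[ord[1]])
  for (j in seq_along(ord)) {
    i <- ord[j]
    gain <- (phys_max[i] - phys_min[i]) / (dig_max[i] - dig_min[i])
    data[j, ] <- ((sig[[i]] - dig_min[i]) * gain + phys_min[i]) *
      unit_scale(phys_dim[i])
  }
  subject <- if (nzchar(patient)) strsplit(patient, " ")[[1]][1] else
    sub("\\.edf$", "", basename(path), ignore.case = TRUE)
  eeg_recording(data, rate, subject_id = subject)
}

#' Write a recording to EDF (synthetic-fixture writer)
#'
#' Writes a plain EDF file readable by [read_edf()].  The default physical
#' range of +/-800 microvolts bounds the 16-bit quantization step at about
#' 0.024 uV; samples outside the range are clipped with a warning.
#'
#' @param rec an [eeg_recording] with an integer sampling rate and a whole
#'   number of seconds of data.
#' @param path output path.
#' @param physical_max symmetric physical range bound in microvolts.
#' @return `path`, invisibly.
#' @export
write_fixture_edf <- function(rec, path, physical_max = 800) {
  stopifnot(inherits(rec, "eeg_recording"))
  rate <- rec$sampling_rate_hz
  if (rate != round(rate)) stop("EDF writer requires an integer sampling rate")
  n_records <- ncol(rec$data) %/% rate
  if (n_records * rate != ncol(rec$data))
    stop("EDF writer requires a whole number of seconds of data")
  ns <- nrow(rec$data)

  x <- rec$data
  if (any(abs(x) > physical_max)) {
    warning("samples clipped to +/-", physical_max, " uV for EDF export")
    x <- pmin(pmax(x, -physical_max), physical_max)
  }
  dmin <- -32768; dmax <- 32767
  dig <- round((x + physical_max) / (2 * physical_max) * (dmax - dmin) + dmin)

  con <- file(path, "wb")
  on.exit(close(con))
  wr <- function(s, n) writeBin(charToRaw(edf_pad(s, n)), con)
  wr("0", 8)
  wr(rec$subject_id, 80)
  wr("plvdx synthetic", 80)
  wr("01.01.20", 8); wr("00.00.00", 8)
  wr(256 + ns * 256, 8)
  wr("", 44)
  wr(n_records, 8)
  wr("1", 8)                       # one-second data records
  wr(ns, 4)
  for (lab in rec$channel_labels) wr(lab, 16)
  for (i in seq_len(ns)) wr("", 80)
  for (i in seq_len(ns)) wr("uV", 8)
  for (i in seq_len(ns)) wr(-physical_max, 8)
  for (i in seq_len(ns)) wr(physical_max, 8)
  for (i in seq_len(ns)) wr(dmin, 8)
  for (i in seq_len(ns)) wr(dmax, 8)
  for (i in seq_len(ns)) wr("", 80)
  for (i in seq_len(ns)) wr(rate, 8)
  for (i in seq_len(ns)) wr("", 32)
  for (r in seq_len(n_records)) {
    idx <- ((r - 1) * rate + 1):(r * rate)
    for (i in seq_len(ns))
      writeBin(as.integer(dig[i, idx]), con, size = 2, endian = "little")
  }
  invisible(path)
}
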