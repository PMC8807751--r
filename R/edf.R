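# Minimal European Data Format (EDF) reader: standard 16-bit EDF,
# continuous signals.  Annotation channels ("EDF Annotations") are
# excluded from the signal matrix; cue events are supplied separately
# (matrix container or `events` argument downstream).

edf_ascii <- function(con, n) trimws(rawToChar(readBin(con, "raw", n)))

#' Read a standard EDF file
#'
#' Parses the 256-byte header, per-signal headers, and 16-bit
#' little-endian data records, applying the physical/digital calibration
#' per signal.  All retained signals must share one sampling rate.
#'
#' @param path path to an EDF file.
#' @return an [eeg_recording()] with an empty event table.
#' @export
read_edf <- function(path) {
  con <- file(path, "rb")
  on.exit(close(con))
  version <- edf_ascii(con, 8)
  edf_ascii(con, 80); edf_ascii(con, 80)          # patient / recording id
  edf_ascii(con, 8); edf_ascii(con, 8)            # start date / time
  header_bytes <- as.integer(edf_ascii(con, 8))
  edf_ascii(con, 44)                              # reserved
  n_records <- as.integer(edf_ascii(con, 8))
  record_dur <- as.numeric(edf_ascii(con, 8))
  ns <- as.integer(edf_ascii(con, 4))
  if (is.na(ns) || ns < 1) stop2("unreadable EDF header")
  fld <- function(w) vapply(seq_len(ns), function(i) edf_ascii(con, w), character(1))
  labels   <- fld(16)
  fld(80); fld(8)                                 # transducer, dimension
  phys_min <- as.numeric(fld(8)); phys_max <- as.numeric(fld(8))
  dig_min  <- as.numeric(fld(8)); dig_max  <- as.numeric(fld(8))
  fld(80)                                         # prefiltering
  nsamp    <- as.integer(fld(8))
  fld(32)                                         # reserved
  keep <- labels != "EDF Annotations"
  if (!any(keep)) stop2("EDF file contains no data signals")
  if (record_dur <= 0) stop2("invalid sampling rate")
  rates <- nsamp[keep] / record_dur
  if (length(unique(rates)) != 1L)
    stop2("signals with differing sampling rates are not supported")
  gain <- (phys_max - phys_min) / pmax(dig_max - dig_min, 1)
  off  <- phys_min - gain * dig_min
  sig <- matrix(0, sum(keep), n_records * nsamp[keep][1])
  rown <- 0L
  # data records: for each record, each signal's samples consecutively
  per_rec <- sum(nsamp)
  for (r in seq_len(n_records)) {
    buf <- readBin(con, "integer", per_rec, size = 2L, signed = TRUE,
                   endian = "little")
    if (length(buf) < per_rec) stop2("unreadable file: truncated EDF record")
    pos <- 0L; rown <- 0L
    for (s in seq_len(ns)) {
      chunk <- buf[(pos + 1):(pos + nsamp[s])]
      pos <- pos + nsamp[s]
      if (!keep[s]) next
      rown <- rown + 1L
      cols <- ((r - 1L) * nsamp[s] + 1):((r) * nsamp[s])
      sig[rown, cols] <- chunk * gain[s] + off[s]
    }
  }
  eeg_recording(sig, rates[1], labels[keep])
}

# EDF writer used to build round-trip fixtures at run time (binary files
# are never stored in the package sources).
#' Write a standard EDF file
#'
#' Writes 16-bit EDF with one data record per second.  The signal is
#' clipped to the stated physical range.  Intended for fixtures and for
#' exporting simulated data; events are not written (standard EDF has no
#' event channel).
#'
#' @param rec an [eeg_recording()]; the sample count must be a multiple
#'   of the sampling rate.
#' @param path output path.
#' @param phys_range symmetric physical range in microvolts (default 3276.7).
#' @return `path`, invisibly.
#' @export
write_edf <- function(rec, path, phys_range = 3276.7) {
  stopifnot(inherits(rec, "eeg_recording"))
  rate <- rec$sampling_rate
  if (rate != round(rate)) stop2("write_edf needs an integer sampling rate")
  n <- ncol(rec$signal)
  if (n %% rate != 0) stop2("sample count must be a multiple of the rate")
  n_records <- n / rate
  ns <- nrow(rec$signal)
  con <- file(path, "wb")
  on.exit(close(con))
  pad <- function(x, w) {
    s <- sprintf("%-*s", w, as.character(x))
    writeBin(charToRaw(substr(s, 1, w)), con)
  }
  pad("0", 8)
  pad("anonymous", 80); pad("simulated", 80)
  pad("01.01.00", 8); pad("00.00.00", 8)
  pad(256 + 256 * ns, 8); pad("", 44)
  pad(n_records, 8); pad(1, 8); pad(ns, 4)
  for (nm in rec$channel_names) pad(nm, 16)
  for (i in seq_len(ns)) pad("", 80)
  for (i in seq_len(ns)) pad("uV", 8)
  for (i in seq_len(ns)) pad(sprintf("%g", -phys_range), 8)
  for (i in seq_len(ns)) pad(sprintf("%g", phys_range), 8)
  for (i in seq_len(ns)) pad(-32767, 8)
  for (i in seq_len(ns)) pad(32767, 8)
  for (i in seq_len(ns)) pad("", 80)
  for (i in seq_len(ns)) pad(rate, 8)
  for (i in seq_len(ns)) pad("", 32)
  scale <- 32767 / phys_range
  for (r in seq_len(n_records)) {
    cols <- ((r - 1) * rate + 1):(r * rate)
    for (s in seq_len(ns)) {
      d <- round(pmin(pmax(rec$signal[s, cols], -phys_range), phys_range) * scale)
      writeBin(as.integer(d), con, size = 2L, endian = "little")
    }
  }
  invisible(path)
}
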