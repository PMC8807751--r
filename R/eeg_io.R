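#' Continuous EEG recordings
#'
#' An `eeg_recording` holds a continuous multichannel signal (channels x
#' samples, microvolts), its sampling rate, and cue events as
#' (onset_sample, code) rows.  Onsets are 0-based sample indices into the
#' signal; codes are small integers that [epoch_trials()] maps to class
#' labels.
#'
#' @param signal numeric matrix, channels x samples.
#' @param sampling_rate sampling rate in Hz, positive.
#' @param channel_names character vector, one name per signal row.
#' @param events data frame with columns `onset_sample`, `code` (may have
#'   zero rows).
#' @return an object of class `eeg_recording`.
#' @export
eeg_recording <- function(signal, sampling_rate, channel_names,
                          events = data.frame(onset_sample = integer(),
                                              code = integer())) {
  signal <- as.matrix(signal)
  if (!is.numeric(sampling_rate) || length(sampling_rate) != 1 ||
      !is.finite(sampling_rate) || sampling_rate <= 0)
    stop2("invalid sampling rate")
  if (nrow(signal) != length(channel_names))
    stop2("number of signal rows must equal number of channel names")
  events <- as.data.frame(events)
  if (nrow(events)) {
    if (!all(c("onset_sample", "code") %in% names(events)))
      stop2("events need columns onset_sample, code")
    if (any(events$onset_sample < 0 | events$onset_sample >= ncol(signal)))
      stop2("event onsets must lie within the recording")
  }
  structure(list(signal = signal, sampling_rate = sampling_rate,
                 channel_names = as.character(channel_names),
                 events = events),
            class = "eeg_recording")
}

#' @export
print.eeg_recording <- function(x, ...) {
  cat(sprintf("<eeg_recording> %d channels x %d samples @ %g Hz, %d events\n",
              nrow(x$signal), ncol(x$signal), x$sampling_rate, nrow(x$events)))
  invisible(x)
}

#' Load a continuous EEG recording
#'
#' Reads either European Data Format (`.edf`, 16-bit standard EDF) or the
#' package's plain-text JSON matrix container (see
#' [write_eeg_container()]).  If a montage is given, channels are reordered
#' to montage order; channels present in the file but absent from the
#' montage are dropped with a message, and missing montage channels are an
#' error.
#'
#' @param path file path.
#' @param format `"auto"` (by extension), `"edf"` or `"container"`.
#' @param montage optional [montage()] used to fix channel order.
#' @return an [eeg_recording()].
#' @export
load_recording <- function(path, format = c("auto", "edf", "container"),
                           montage = NULL) {
  format <- match.arg(format)
  if (!file.exists(path)) stop2("file not found: ", path)
  if (format == "auto")
    format <- if (grepl("\\.edf$", path, ignore.case = TRUE)) "edf" else "container"
  rec <- if (format == "edf") read_edf(path) else read_eeg_container(path)
  if (!is.null(montage)) rec <- reorder_channels(rec, montage)
  rec
}

reorder_channels <- function(rec, montage) {
  idx <- match(montage$name, rec$channel_names)
  if (anyNA(idx))
    stop2("channel count mismatch with requested montage: missing ",
          paste(montage$name[is.na(idx)], collapse = ", "))
  extra <- setdiff(rec$channel_names, montage$name)
  if (length(extra))
    message("dropping channels not in montage: ", paste(extra, collapse = ", "))
  rec$signal <- rec$signal[idx, , drop = FALSE]
  rec$channel_names <- montage$name
  rec
}

#' Plain-text matrix container for EEG fixtures
#'
#' A JSON container holding one signal array (channels x samples), the
#' event table, the sampling rate and channel names.  Used for small
#' fixtures and for round-tripping simulated data; EDF covers real
#' recordings.
#'
#' @param rec an [eeg_recording()].
#' @param path output / input file path.
#' @return `write_eeg_container` returns `path` invisibly;
#'   `read_eeg_container` returns an [eeg_recording()].
#' @export
write_eeg_container <- function(rec, path) {
  stopifnot(inherits(rec, "eeg_recording"))
  obj <- list(rate = rec$sampling_rate,
              channels = rec$channel_names,
              signal = unname(apply(rec$signal, 1L, identity, simplify = FALSE)),
              events = rec$events)
  jsonlite::write_json(obj, path, digits = NA, auto_unbox = TRUE)
  invisible(path)
}

#' @rdname write_eeg_container
#' @export
read_eeg_container <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  if (is.null(obj$rate) || obj$rate <= 0) stop2("invalid sampling rate")
  sig <- obj$signal
  if (is.list(sig)) sig <- do.call(rbind, sig) else sig <- rbind(sig)
  ev <- obj$events
  if (is.null(ev) || length(ev) == 0 || NROW(ev) == 0)
    ev <- data.frame(onset_sample = integer(), code = integer())
  eeg_recording(sig, obj$rate, obj$channels, ev)
}

#' Zero-phase band-pass filter
#'
#' Butterworth band-pass applied forward and backward
#' ([signal::filtfilt()]), so the response is zero-phase and cue/event
#' alignment is preserved.  Default band 4-40 Hz, order 4.
#'
#' @param rec an [eeg_recording()].
#' @param low,high band edges in Hz; `0 < low < high < rate/2` required.
#' @param order Butterworth prototype order (default 4).
#' @return filtered [eeg_recording()] of identical shape.
#' @export
bandpass_filter <- function(rec, low = 4, high = 40, order = 4) {
  stopifnot(inherits(rec, "eeg_recording"))
  nyq <- rec$sampling_rate / 2
  if (!(low > 0 && low < high && high < nyq))
    stop2("band outside Nyquist limit: need 0 < low < high < ", nyq)
  bf <- signal::butter(order, c(low, high) / nyq, type = "pass")
  rec$signal <- t(apply(rec$signal, 1L, function(ch) signal::filtfilt(bf, ch)))
  rec
}

#' Trial sets
#'
#' A `trial_set` is the epoched, labelled form of a recording: an
#' L x N x F array (trials x channels x samples) with one integer label in
#' 0..3 per trial (left hand, right hand, feet, tongue by convention).
#'
#' @param trials numeric array L x N x F.
#' @param labels integer vector of length L with values in 0..3.
#' @param sampling_rate Hz.
#' @param channel_names optional channel names (length N).
#' @return an object of class `trial_set`.
#' @export
trial_set <- function(trials, labels, sampling_rate, channel_names = NULL) {
  trials <- as.array(trials)
  if (length(dim(trials)) != 3L) stop2("trials must be an L x N x F array")
  labels <- as.integer(labels)
  if (dim(trials)[1] != length(labels)) stop2("one label per trial required")
  if (length(labels) && !all(labels %in% 0:3))
    stop2("labels must be integers in 0..3")
  if (!is.null(channel_names) && length(channel_names) != dim(trials)[2])
    stop2("one channel name per channel required")
  structure(list(trials = trials, labels = labels,
                 sampling_rate = sampling_rate,
                 channel_names = channel_names),
            class = "trial_set")
}

#' @export
print.trial_set <- function(x, ...) {
  d <- dim(x$trials)
  cat(sprintf("<trial_set> %d trials x %d channels x %d samples @ %g Hz\n",
              d[1], d[2], d[3], x$sampling_rate))
  if (d[1]) {
    tb <- table(factor(x$labels, levels = 0:3))
    cat("  labels:", paste(sprintf("%s=%d", names(tb), tb), collapse = " "), "\n")
  }
  invisible(x)
}

#' Cut cue-locked trials from a recording
#'
#' Each event becomes one trial covering the half-open sample window
#' `[onset - pre_cue*rate, onset - pre_cue*rate + length*rate)` (0-based,
#' start-inclusive).  Trials whose window leaves the recording are dropped
#' with a warning.  Event codes are mapped to class labels 0..3 through
#' `label_map`.
#'
#' @param rec an [eeg_recording()] with labelled events.
#' @param pre_cue seconds before the cue at which the window starts
#'   (default 0.5).
#' @param length total trial length in seconds (default 4.5).
#' @param label_map named vector mapping event codes to labels 0..3;
#'   `NULL` means codes are already 0..3.
#' @return a [trial_set()].
#' @export
epoch_trials <- function(rec, pre_cue = 0.5, length = 4.5, label_map = NULL) {
  stopifnot(inherits(rec, "eeg_recording"))
  if (pre_cue < 0 || length <= pre_cue) stop2("need pre_cue >= 0 and length > pre_cue")
  ev <- rec$events
  if (!nrow(ev)) stop2("no events with labels")
  codes <- ev$code
  if (!is.null(label_map)) {
    lab <- unname(label_map[as.character(codes)])
    if (anyNA(lab)) stop2("event codes without label mapping: ",
                          paste(unique(codes[is.na(lab)]), collapse = ", "))
  } else lab <- codes
  rate <- rec$sampling_rate
  nF <- round(length * rate)
  start <- round(ev$onset_sample - pre_cue * rate)   # 0-based
  ok <- start >= 0 & (start + nF) <= ncol(rec$signal)
  if (any(!ok))
    warning(sum(!ok), " trial(s) dropped: window leaves the recording")
  keep <- which(ok)
  out <- array(0, c(base::length(keep), nrow(rec$signal), nF))
  for (i in seq_along(keep)) {
    s <- start[keep[i]]
    out[i, , ] <- rec$signal[, (s + 1):(s + nF), drop = FALSE]
  }
  trial_set(out, lab[keep], rate, rec$channel_names)
}

#' Standard-scale a trial set
#'
#' Centres and scales each channel to mean 0 and standard deviation 1,
#' pooling over all trials and samples.  Channels with (near-)zero
#' variance are mapped to zeros via an epsilon guard rather than blowing
#' up.
#'
#' @param ts a [trial_set()].
#' @param eps variance guard (default 1e-12).
#' @return the standardized [trial_set()]; shape and labels unchanged.
#' @export
standardize <- function(ts, eps = .eps) {
  stopifnot(inherits(ts, "trial_set"))
  d <- dim(ts$trials)
  if (d[1] == 0) stop2("empty trial set")
  for (ch in seq_len(d[2])) {
    v <- ts$trials[, ch, ]
    mu <- mean(v)
    sd_ <- stats::sd(as.vector(v))
    if (!is.finite(sd_) || sd_ < eps) {
      message("channel ", ch, " is (near-)constant; standardized to zeros")
      ts$trials[, ch, ] <- 0
    } else {
      ts$trials[, ch, ] <- (v - mu) / sd_
    }
  }
  ts
}
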