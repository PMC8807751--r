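#' Frequency band specifications
#'
#' A band spec is an ordered list of (low, high) Hz sub-bands.  The
#' default partitions the 4-40 Hz analysis band into 11 contiguous
#' equal-width sub-bands, matching one differential-entropy feature per
#' sub-band per channel.
#'
#' @param low,high outer band edges in Hz.
#' @param n number of contiguous equal-width sub-bands.
#' @return a `band_spec`: 2-column matrix (low, high), one row per band.
#' @export
band_spec <- function(low = 4, high = 40, n = 11) {
  if (n < 1 || low >= high) stop2("need n >= 1 and low < high")
  edges <- seq(low, high, length.out = n + 1)
  structure(cbind(low = edges[-(n + 1)], high = edges[-1]), class = "band_spec")
}

#' @param bands a 2-column matrix of explicit (low, high) rows.
#' @rdname band_spec
#' @export
as_band_spec <- function(bands) {
  bands <- as.matrix(bands)
  if (ncol(bands) != 2 || nrow(bands) < 1) stop2("empty band list")
  if (any(bands[, 1] >= bands[, 2])) stop2("every band needs low < high")
  colnames(bands) <- c("low", "high")
  structure(bands, class = "band_spec")
}

# Feature tensors are L x N x C x T numeric arrays (trials x nodes x
# feature channels x time segments) with metadata attributes.
feature_tensor <- function(values, kind, bands = NULL, segment = NULL,
                           node_names = NULL) {
  stopifnot(length(dim(values)) == 4L)
  if (!all(is.finite(values))) stop2("feature tensor contains non-finite values")
  structure(values, class = c("feature_tensor", "array"), kind = kind,
            bands = bands, segment = segment, node_names = node_names)
}

#' @export
print.feature_tensor <- function(x, ...) {
  d <- dim(x)
  cat(sprintf("<feature_tensor:%s> %d trials x %d nodes x %d channels x %d segments\n",
              attr(x, "kind"), d[1], d[2], d[3], d[4]))
  invisible(x)
}

# split an epoch of F samples into floor(F / seg_len) full segments
segment_index <- function(n_samples, seg_len) {
  n_seg <- floor(n_samples / seg_len)
  if (n_seg < 1) stop2("segment longer than the epoch")
  if (n_samples %% seg_len != 0)
    message("dropping ", n_samples - n_seg * seg_len,
            " trailing samples that do not fill a segment")
  lapply(seq_len(n_seg), function(s) ((s - 1) * seg_len + 1):(s * seg_len))
}

band_filters <- function(bands, rate, order = 4) {
  nyq <- rate / 2
  lapply(seq_len(nrow(bands)), function(i) {
    hi <- min(bands[i, 2], nyq * 0.99)
    signal::butter(order, c(bands[i, 1], hi) / nyq, type = "pass")
  })
}

#' Differential-entropy features
#'
#' For each trial, channel, sub-band and time segment, computes the
#' differential entropy of the band-filtered segment under a Gaussian
#' model: `DE = 0.5 * log(2 * pi * e * var)`, in nats, with the variance
#' floored at `eps` so silent segments stay finite.
#'
#' @param ts a [trial_set()] (typically already band-passed to 4-40 Hz).
#' @param bands a [band_spec()]; default 11 equal sub-bands of 4-40 Hz.
#' @param segment segment length in seconds (default 0.5); a trailing
#'   partial segment is dropped.
#' @param eps variance floor.
#' @return a `feature_tensor` of shape L x N x n_bands x n_segments.
#' @export
de_features <- function(ts, bands = band_spec(), segment = 0.5, eps = .eps) {
  stopifnot(inherits(ts, "trial_set"))
  bands <- as_band_spec(unclass(bands))
  d <- dim(ts$trials)
  seg_len <- round(segment * ts$sampling_rate)
  segs <- segment_index(d[3], seg_len)
  filts <- band_filters(bands, ts$sampling_rate)
  out <- array(0, c(d[1], d[2], nrow(bands), length(segs)))
  for (tr in seq_len(d[1])) for (ch in seq_len(d[2])) {
    x <- ts$trials[tr, ch, ]
    x <- x - mean(x)          # offset-invariant; avoids DC filter transients
    for (b in seq_len(nrow(bands))) {
      xf <- signal::filtfilt(filts[[b]], x)
      for (s in seq_along(segs)) {
        v <- max(stats::var(xf[segs[[s]]]), eps)
        out[tr, ch, b, s] <- 0.5 * log(2 * pi * exp(1) * v)
      }
    }
  }
  feature_tensor(out, "DE", bands = bands, segment = segment,
                 node_names = ts$channel_names)
}

#' Band-power (PSD) features
#'
#' Periodogram band power per trial, channel, sub-band and time segment.
#' Powers are two-sided-corrected so that summing over a band partition
#' of the full spectrum recovers the segment's mean square (Parseval).
#'
#' @inheritParams de_features
#' @return a `feature_tensor` of shape L x N x n_bands x n_segments.
#' @export
psd_features <- function(ts, bands = band_spec(), segment = 0.5) {
  stopifnot(inherits(ts, "trial_set"))
  bands <- as_band_spec(unclass(bands))
  d <- dim(ts$trials)
  seg_len <- round(segment * ts$sampling_rate)
  segs <- segment_index(d[3], seg_len)
  freqs <- (0:(seg_len - 1)) * ts$sampling_rate / seg_len
  half <- freqs[seq_len(floor(seg_len / 2) + 1)]
  # map each band to its rfft bins: [low, high), last band closed at high
  binsets <- lapply(seq_len(nrow(bands)), function(b) {
    hi_closed <- b == nrow(bands)
    which(half >= bands[b, 1] & (half < bands[b, 2] |
                                   (hi_closed & half <= bands[b, 2])))
  })
  out <- array(0, c(d[1], d[2], nrow(bands), length(segs)))
  for (tr in seq_len(d[1])) for (ch in seq_len(d[2])) {
    x <- ts$trials[tr, ch, ]
    x <- x - mean(x)          # band power about the mean
    for (s in seq_along(segs)) {
      seg <- x[segs[[s]]]
      p <- Mod(stats::fft(seg))^2 / seg_len^2       # two-sided periodogram
      ph <- p[seq_along(half)]
      # fold negative frequencies onto positive bins (except DC/Nyquist)
      dbl <- rep(2, length(half)); dbl[1] <- 1
      if (seg_len %% 2 == 0) dbl[length(half)] <- 1
      ph <- ph * dbl
      for (b in seq_len(nrow(bands)))
        out[tr, ch, b, s] <- sum(ph[binsets[[b]]])
    }
  }
  feature_tensor(out, "PSD", bands = bands, segment = segment,
                 node_names = ts$channel_names)
}

pair_index <- function(node_names, pairs, what) {
  if (is.null(pairs) || nrow(pairs) == 0) stop2("no ", what, " defined")
  a <- match(pairs[[1]], node_names)
  b <- match(pairs[[2]], node_names)
  if (anyNA(a) || anyNA(b)) stop2(what, " reference channels absent from tensor")
  cbind(a, b)
}

#' Hemispheric asymmetry features
#'
#' Differential (DASM), rational (RASM) and concatenated (ASM) asymmetry
#' of differential-entropy features over left/right mirror electrode
#' pairs: `DASM = DE(left) - DE(right)`, `RASM = DE(left) / DE(right)`
#' (denominator epsilon-guarded, sign-preserving), and
#' `ASM = [DASM || RASM]` stacked along the feature-channel axis.
#'
#' @param de a DE `feature_tensor` ([de_features()]).
#' @param m a [montage()] defining `mirror_pairs`.
#' @param kind `"DASM"`, `"RASM"` or `"ASM"`.
#' @param eps guard for near-zero denominators in RASM.
#' @return a `feature_tensor` with one node per mirror pair.
#' @export
asymmetry_features <- function(de, m, kind = c("DASM", "RASM", "ASM"),
                               eps = 1e-6) {
  kind <- match.arg(kind)
  stopifnot(inherits(de, "feature_tensor"))
  idx <- pair_index(attr(de, "node_names") %||% m$name,
                    attr(m, "mirror_pairs"), "mirror pairs")
  v <- unclass(de)
  left <- v[, idx[, 1], , , drop = FALSE]
  right <- v[, idx[, 2], , , drop = FALSE]
  dasm <- left - right
  if (kind == "DASM") out <- dasm
  else {
    den <- right
    small <- abs(den) < eps
    den[small] <- eps * ifelse(den[small] < 0, -1, 1)
    rasm <- left / den
    out <- if (kind == "RASM") rasm else
      abind4(dasm, rasm)                 # ASM: concat along channel axis
  }
  feature_tensor(out, kind, bands = attr(de, "bands"),
                 segment = attr(de, "segment"),
                 node_names = paste(attr(m, "mirror_pairs")$left,
                                    attr(m, "mirror_pairs")$right, sep = "-"))
}

# bind two L x P x C x T arrays along the third (feature channel) axis
abind4 <- function(a, b) {
  da <- dim(a); db <- dim(b)
  out <- array(0, c(da[1], da[2], da[3] + db[3], da[4]))
  out[, , seq_len(da[3]), ] <- a
  out[, , da[3] + seq_len(db[3]), ] <- b
  out
}

#' Caudal asymmetry features
#'
#' Differential caudality: `DCAU = DE(frontal) - DE(posterior)` over the
#' montage's frontal/posterior electrode pairs.
#'
#' @inheritParams asymmetry_features
#' @return a `feature_tensor` with one node per caudal pair.
#' @export
dcau_features <- function(de, m) {
  stopifnot(inherits(de, "feature_tensor"))
  idx <- pair_index(attr(de, "node_names") %||% m$name,
                    attr(m, "caudal_pairs"), "caudal pairs")
  v <- unclass(de)
  out <- v[, idx[, 1], , , drop = FALSE] - v[, idx[, 2], , , drop = FALSE]
  feature_tensor(out, "DCAU", bands = attr(de, "bands"),
                 segment = attr(de, "segment"),
                 node_names = paste(attr(m, "caudal_pairs")$frontal,
                                    attr(m, "caudal_pairs")$posterior, sep = "-"))
}

#' Double-fold node features to the adjacency size
#'
#' Duplicates each node's per-segment feature vector (concatenating it
#' with itself) so its length matches the number of graph nodes, making
#' the node-feature matrix square against the adjacency matrix.  With the
#' default 11 sub-band DE features and 22 electrodes the doubled length
#' is exactly 22.
#'
#' @param ft a `feature_tensor` (L x N x C x T).
#' @param n_nodes target per-node feature length (the adjacency side N).
#' @param pad if `TRUE`, zero-pad after doubling when `2 * C < n_nodes`;
#'   if `FALSE` (default), any mismatch is an error.
#' @return a `feature_tensor` of shape L x N x n_nodes x T.
#' @export
assemble_node_features <- function(ft, n_nodes, pad = FALSE) {
  stopifnot(inherits(ft, "feature_tensor"))
  v <- unclass(ft)
  doubled <- abind4(v, v)
  have <- dim(doubled)[3]
  if (have != n_nodes) {
    if (!pad || have > n_nodes)
      stop2("doubled feature length ", have, " does not match n_nodes ",
            n_nodes, if (!pad) " (padding disabled)")
    padded <- array(0, c(dim(doubled)[1:2], n_nodes, dim(doubled)[4]))
    padded[, , seq_len(have), ] <- doubled
    doubled <- padded
  }
  feature_tensor(doubled, paste0(attr(ft, "kind"), "+folded"),
                 bands = attr(ft, "bands"), segment = attr(ft, "segment"),
                 node_names = attr(ft, "node_names"))
}

#' Export a feature tensor in long format
#'
#' @param ft a `feature_tensor`.
#' @param path optional TSV output path.
#' @return a data frame (trial, node, channel, segment, value), written
#'   to `path` when given.
#' @export
feature_long <- function(ft, path = NULL) {
  d <- dim(ft)
  g <- expand.grid(trial = seq_len(d[1]), node = seq_len(d[2]),
                   channel = seq_len(d[3]), segment = seq_len(d[4]))
  g$value <- as.vector(unclass(ft))
  if (!is.null(path))
    utils::write.table(g, path, sep = "\t", row.names = FALSE, quote = FALSE)
  g
}
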