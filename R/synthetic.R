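# Synthetic motor-imagery EEG with planted block connectivity.  Stands in
# for the four-class sensorimotor-rhythm recordings in every test: 22
# channels at 250 Hz, 4 balanced classes, 4.5 s trials, band-limited
# shared sources with class-dependent per-block gain.

#' Synthetic EEG specification
#'
#' Channels are partitioned into blocks; each block shares one
#' band-limited latent source per trial, so within-block channel pairs
#' are strongly coupled and between-block pairs are not — the planted
#' graph that connectivity estimation must recover.  Class identity
#' scales each block's source amplitude through the gain matrix, giving
#' classes distinct band-power signatures.
#'
#' Channel i in block b of a class-c trial emits
#' `x_i = alpha * gain[c, b] * z_b + beta * eps_i`
#' with `z_b` unit-variance 8-13 Hz filtered noise shared by the block
#' and `eps_i` white noise private to the channel.
#'
#' @param n_channels electrode count (default 22).
#' @param trials_per_class trials per class (default 72; 288 in total).
#' @param sampling_rate Hz (default 250).
#' @param trial_length seconds per trial (default 4.5).
#' @param blocks list of channel index vectors partitioning
#'   `1:n_channels`; default: 4 contiguous near-equal blocks (one per
#'   class).
#' @param alpha shared-source coupling strength (default 1).
#' @param beta private-noise mix (default 0.3).
#' @param gain `n_classes x n_blocks` gain matrix; default 2.0 on the
#'   block matching the class (cyclically), 1.0 elsewhere.
#' @param source_band (low, high) Hz of the latent sources (default
#'   8-13, the mu band).
#' @param noise_sd private noise standard deviation (default 1).
#' @param n_classes number of classes (default 4).
#' @param seed RNG seed.
#' @return a `synthetic_spec` list.
#' @export
synthetic_spec <- function(n_channels = 22, trials_per_class = 72,
                           sampling_rate = 250, trial_length = 4.5,
                           blocks = NULL, alpha = 1, beta = 0.3,
                           gain = NULL, source_band = c(8, 13),
                           noise_sd = 1, n_classes = 4, seed = 1) {
  if (trials_per_class < 1) stop2("trials_per_class must be >= 1")
  if (alpha < 0 || beta < 0) stop2("alpha and beta must be >= 0")
  blocks <- blocks %||% default_blocks(n_channels, 4)
  idx <- sort(unlist(blocks))
  if (length(idx) != n_channels || any(idx != seq_len(n_channels)))
    stop2("blocks must partition the channel set")
  B <- length(blocks)
  gain <- gain %||% (1 + diag(1, n_classes)[, ((seq_len(B) - 1) %% n_classes) + 1,
                                            drop = FALSE])
  gain <- as.matrix(gain)
  if (nrow(gain) != n_classes || ncol(gain) != B)
    stop2("gain must be n_classes x n_blocks")
  structure(list(n_channels = n_channels, trials_per_class = trials_per_class,
                 sampling_rate = sampling_rate, trial_length = trial_length,
                 blocks = blocks, alpha = alpha, beta = beta, gain = gain,
                 source_band = source_band, noise_sd = noise_sd,
                 n_classes = n_classes, seed = seed),
            class = "synthetic_spec")
}

default_blocks <- function(n_channels, n_blocks) {
  sizes <- rep(n_channels %/% n_blocks, n_blocks)
  extra <- n_channels %% n_blocks
  if (extra) sizes[seq_len(extra)] <- sizes[seq_len(extra)] + 1L
  split(seq_len(n_channels), rep(seq_len(n_blocks), sizes))
}

#' Planted ground-truth channel graph
#'
#' Binary block-diagonal adjacency: an edge if and only if two channels
#' share a block; zero diagonal.
#'
#' @param spec a [synthetic_spec()].
#' @return a binary `adjacency_matrix`.
#' @export
make_planted_graph <- function(spec) {
  stopifnot(inherits(spec, "synthetic_spec"))
  N <- spec$n_channels
  A <- matrix(0, N, N)
  for (b in spec$blocks) A[b, b] <- 1
  diag(A) <- 0
  adjacency_matrix(A, "planted_blocks")
}

#' Simulate labelled EEG trials
#'
#' Draws `trials_per_class * n_classes` trials per the spec (labels
#' interleaved 0,1,2,3,...), each built from per-block shared
#' band-limited sources plus private channel noise.  Fully reproducible
#' from `spec$seed`.
#'
#' @param spec a [synthetic_spec()].
#' @return a [trial_set()] with channel names `ch01`, `ch02`, ...
#' @export
simulate_trials <- function(spec) {
  stopifnot(inherits(spec, "synthetic_spec"))
  rate <- spec$sampling_rate
  nF <- round(spec$trial_length * rate)
  L <- spec$trials_per_class * spec$n_classes
  labels <- rep(0:(spec$n_classes - 1), spec$trials_per_class)
  N <- spec$n_channels
  bf <- signal::butter(4, spec$source_band / (rate / 2), type = "pass")
  # pad so filter transients do not leak into the kept window
  pad <- rate
  out <- array(0, c(L, N, nF))
  with_seed(spec$seed, {
    for (tr in seq_len(L)) {
      cls <- labels[tr] + 1L
      for (b in seq_along(spec$blocks)) {
        z <- signal::filtfilt(bf, stats::rnorm(nF + 2 * pad))
        z <- z[(pad + 1):(pad + nF)]
        z <- z / max(stats::sd(z), .eps)
        g <- spec$alpha * spec$gain[cls, b]
        for (ch in spec$blocks[[b]]) {
          out[tr, ch, ] <- g * z +
            spec$beta * stats::rnorm(nF, sd = spec$noise_sd)
        }
      }
    }
  })
  trial_set(out, labels, rate, sprintf("ch%02d", seq_len(N)))
}

#' Write a simulated trial set with provenance
#'
#' Stores the trials in the matrix-container JSON format (one file per
#' trial set, trials concatenated along time with an event row per
#' trial onset) plus a JSON sidecar holding the generating
#' [synthetic_spec()] including its seed.
#'
#' @param ts a [trial_set()] from [simulate_trials()].
#' @param spec the generating [synthetic_spec()].
#' @param path output path for the container; the sidecar gets
#'   `paste0(path, ".spec.json")`.
#' @return `path`, invisibly.
#' @export
write_simulated <- function(ts, spec, path) {
  d <- dim(ts$trials)
  sig <- matrix(aperm(ts$trials, c(2, 3, 1)), d[2], d[1] * d[3])
  ev <- data.frame(onset_sample = (seq_len(d[1]) - 1L) * d[3],
                   code = ts$labels)
  rec <- eeg_recording(sig, ts$sampling_rate, ts$channel_names, ev)
  write_eeg_container(rec, path)
  side <- spec
  side$blocks <- lapply(side$blocks, as.integer)
  class(side) <- NULL
  jsonlite::write_json(side, paste0(path, ".spec.json"), digits = NA,
                       auto_unbox = TRUE)
  invisible(path)
}
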