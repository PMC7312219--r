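#' Configuration for the synthetic EEG generator
#'
#' Describes a two-class multichannel EEG-like dataset in which the
#' class-discriminative rhythm is confined to a known subset of channels.
#' All other channels carry only background activity (pink noise plus a
#' 10 Hz alpha component), so downstream channel selection has a known
#' ground truth.
#'
#' @param n_channels Number of channels.
#' @param informative_channels Integer indices (1-based) of the channels
#'   that carry the seizure-class rhythm. Must lie in `1..n_channels`.
#' @param n_per_class Epochs generated per class (the output is balanced).
#' @param fs Sampling rate in Hz.
#' @param duration_s Epoch length in seconds; `fs * duration_s` must be an
#'   integer number of samples.
#' @param snr Ratio of the class-signal RMS to the background RMS on the
#'   informative channels of seizure epochs. `snr = 0` produces two
#'   identical class-conditional generators.
#' @param seed Integer seed; expanded into independent per-epoch substreams
#'   so the result does not depend on generation order.
#' @return An object of class `synth_config`.
#' @seealso [generate_epochs()]
#' @export
synth_config <- function(n_channels = 8, informative_channels = 1L,
                         n_per_class = 40, fs = 128, duration_s = 6,
                         snr = 3, seed = 1) {
  n_channels <- assert_count(n_channels, "n_channels")
  n_per_class <- assert_count(n_per_class, "n_per_class")
  fs <- assert_number(fs, "fs", min = 1)
  duration_s <- assert_number(duration_s, "duration_s", min = 0)
  snr <- assert_number(snr, "snr", min = 0)
  n_samples <- fs * duration_s
  if (abs(n_samples - round(n_samples)) > 1e-9) {
    stop("fs * duration_s must be an integer number of samples", call. = FALSE)
  }
  informative_channels <- sort(unique(as.integer(informative_channels)))
  if (length(informative_channels) == 0 && snr > 0) {
    stop("informative_channels must be non-empty when snr > 0", call. = FALSE)
  }
  if (length(informative_channels) > 0 &&
      (min(informative_channels) < 1L ||
       max(informative_channels) > n_channels)) {
    stop("informative_channels must lie in 1..n_channels", call. = FALSE)
  }
  structure(
    list(n_channels = n_channels,
         informative_channels = informative_channels,
         n_per_class = n_per_class, fs = fs, duration_s = duration_s,
         snr = snr, seed = seed, n_samples = as.integer(round(n_samples))),
    class = "synth_config"
  )
}

#' Pink (1/f) noise
#'
#' Generates zero-mean noise whose power spectral density decays
#' approximately as 1/f, by spectrally shaping Gaussian white noise
#' (each positive Fourier bin scaled by \eqn{1/\sqrt{f}}). Output is
#' standardized to unit sample standard deviation.
#'
#' @param n_samples Length of the sequence (>= 2).
#' @param seed Integer seed; identical seeds give identical output.
#' @return Numeric vector of length `n_samples`.
#' @export
pink_noise <- function(n_samples, seed) {
  n_samples <- assert_count(n_samples, "n_samples", min = 2L)
  with_seed(seed, {
    w <- rnorm(n_samples)
    spec <- fft(w)
    # cycles/sample frequency of each DFT bin; DC removed outright
    k <- c(0, pmin(1:(n_samples - 1), n_samples - (1:(n_samples - 1))))
    scale <- c(0, 1 / sqrt(k[-1] / n_samples))
    x <- Re(fft(spec * scale, inverse = TRUE)) / n_samples
    x <- x - mean(x)
    x / sd(x)
  })
}

#' Spike-wave surrogate rhythm
#'
#' A sharpened 3 Hz sinusoid standing in for the ictal spike-and-wave
#' pattern: a sine at `f0` is cubed (introducing a third harmonic so that
#' both energy and fractal-dimension features respond) and renormalized to
#' unit peak amplitude.
#'
#' @param fs Sampling rate in Hz.
#' @param duration_s Duration in seconds.
#' @param f0 Fundamental frequency in Hz; must satisfy `0 < f0 < fs/2`.
#' @param phase Phase offset in radians.
#' @return Numeric vector of length `fs * duration_s` with `max(abs(.)) == 1`.
#' @export
spike_wave <- function(fs, duration_s, f0 = 3, phase = 0) {
  fs <- assert_number(fs, "fs", min = 1)
  duration_s <- assert_number(duration_s, "duration_s", min = 0)
  f0 <- assert_number(f0, "f0")
  if (f0 <= 0 || f0 >= fs / 2) {
    stop("f0 must satisfy 0 < f0 < fs/2 (aliasing)", call. = FALSE)
  }
  n <- as.integer(round(fs * duration_s))
  t <- (seq_len(n) - 1) / fs
  s <- sin(2 * pi * f0 * t + phase)^3
  s / max(abs(s))
}

#' Generate a balanced two-class synthetic EEG dataset
#'
#' Each epoch's background is per-channel pink noise plus a 10 Hz alpha
#' sinusoid at 0.3 relative RMS (random phase per epoch). Seizure-class
#' epochs additionally carry the [spike_wave()] rhythm, scaled to
#' `snr * background RMS`, on the informative channels only. One global
#' seed is expanded into per-epoch substreams via a counter.
#'
#' @param config A [synth_config()].
#' @return An `epoch_set`: list with `data` (array channels x samples x
#'   epochs), `labels` (integer, 0 = seizure-free, 1 = seizure),
#'   `fs`, `channel_labels`.
#' @export
generate_epochs <- function(config) {
  stopifnot(inherits(config, "synth_config"))
  if (config$snr > 0 && length(config$informative_channels) == 0) {
    stop("informative_channels must be non-empty when snr > 0", call. = FALSE)
  }
  n_ep <- 2L * config$n_per_class
  n <- config$n_samples
  C <- config$n_channels
  data <- array(0, dim = c(C, n, n_ep))
  labels <- rep(c(0L, 1L), each = config$n_per_class)
  t <- (seq_len(n) - 1) / config$fs
  bg_rms <- sqrt(1 + 0.3^2)   # pink (sd 1) + alpha (RMS 0.3), independent
  for (i in seq_len(n_ep)) {
    ep_seed <- substream_seed(config$seed, i)
    phases <- with_seed(ep_seed, runif(C + 1L, 0, 2 * pi))
    for (ch in seq_len(C)) {
      pn <- pink_noise(n, substream_seed(ep_seed, ch))
      alpha <- 0.3 * sqrt(2) * sin(2 * pi * 10 * t + phases[ch])
      data[ch, , i] <- pn + alpha
    }
    if (labels[i] == 1L && config$snr > 0) {
      sw <- spike_wave(config$fs, config$duration_s, f0 = 3,
                       phase = phases[C + 1L])
      sw <- sw * config$snr * bg_rms / sqrt(mean(sw^2))
      for (ch in config$informative_channels) {
        data[ch, , i] <- data[ch, , i] + sw
      }
    }
  }
  epoch_set(data, labels, config$fs,
            channel_labels = paste0("CH", seq_len(C)))
}

#' Construct an epoch set
#'
#' Container for a balanced set of fixed-length multichannel EEG epochs
#' with class labels.
#'
#' @param data Numeric array, channels x samples x epochs.
#' @param labels Integer vector (one per epoch), 0 = seizure-free,
#'   1 = seizure.
#' @param fs Sampling rate in Hz.
#' @param channel_labels Character vector of channel names.
#' @return An object of class `epoch_set`.
#' @export
epoch_set <- function(data, labels, fs, channel_labels = NULL) {
  stopifnot(is.array(data), length(dim(data)) == 3L)
  labels <- as.integer(labels)
  if (length(labels) != dim(data)[3]) {
    stop("one label per epoch required", call. = FALSE)
  }
  if (!all(labels %in% c(0L, 1L))) {
    stop("labels must be 0 (seizure-free) or 1 (seizure)", call. = FALSE)
  }
  if (is.null(channel_labels)) {
    channel_labels <- paste0("CH", seq_len(dim(data)[1]))
  }
  if (length(channel_labels) != dim(data)[1] ||
      anyDuplicated(channel_labels)) {
    stop("channel_labels must be unique, one per channel", call. = FALSE)
  }
  structure(list(data = data, labels = labels, fs = fs,
                 channel_labels = as.character(channel_labels)),
            class = "epoch_set")
}

#' @export
print.epoch_set <- function(x, ...) {
  d <- dim(x$data)
  cat(sprintf(
    "<epoch_set> %d epochs (%d seizure / %d seizure-free), %d channels x %d samples @ %g Hz\n",
    d[3], sum(x$labels == 1L), sum(x$labels == 0L), d[1], d[2], x$fs))
  invisible(x)
}

#' @export
`[.epoch_set` <- function(x, i) {
  epoch_set(x$data[, , i, drop = FALSE], x$labels[i], x$fs, x$channel_labels)
}
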