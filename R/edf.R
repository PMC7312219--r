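# EDF (European Data Format) input/output, epoching from seizure
# annotations, and integer-ratio downsampling.
#
# The reader/writer covers plain 16-bit EDF (no EDF+ annotations), which is
# what the CHB-MIT scalp recordings use. No EDF package is available in this
# R stack, so the fixed-layout header is parsed directly.

EDF_HEADER_BYTES <- 256L
EDF_PER_SIGNAL_BYTES <- 256L
EDF_DIG_MIN <- -32768
EDF_DIG_MAX <- 32767

# Format a number into at most `width` ASCII characters, canonically:
# parsing the result and re-formatting reproduces the same string.
format_edf_num <- function(x, width = 8L) {
  for (digits in 7:1) {
    s <- sprintf("%.*g", digits, x)
    if (nchar(s) <= width) return(s)
  }
  stop("cannot format number into EDF field", call. = FALSE)
}

pad_field <- function(s, width) {
  s <- as.character(s)
  if (nchar(s) > width) s <- substr(s, 1L, width)
  formatC(s, width = -width)
}

#' Construct a continuous multichannel recording
#'
#' @param signals Numeric matrix, channels x samples (all channels share one
#'   length and sampling rate), or a list of equal-length numeric vectors.
#' @param fs Sampling rate in Hz.
#' @param channel_labels Unique channel names, in order.
#' @return Object of class `recording`.
#' @export
recording <- function(signals, fs, channel_labels = NULL) {
  if (is.list(signals)) {
    lens <- lengths(signals)
    if (length(unique(lens)) != 1L) {
      stop("all channels must share one length", call. = FALSE)
    }
    signals <- do.call(rbind, signals)
  }
  stopifnot(is.matrix(signals))
  if (is.null(channel_labels)) {
    channel_labels <- paste0("CH", seq_len(nrow(signals)))
  }
  if (anyDuplicated(channel_labels) ||
      length(channel_labels) != nrow(signals)) {
    stop("channel labels must be unique, one per signal", call. = FALSE)
  }
  structure(list(signals = signals, fs = fs,
                 channel_labels = as.character(channel_labels)),
            class = "recording")
}

#' @export
print.recording <- function(x, ...) {
  cat(sprintf("<recording> %d channels x %d samples @ %g Hz (%.1f s)\n",
              nrow(x$signals), ncol(x$signals), x$fs,
              ncol(x$signals) / x$fs))
  invisible(x)
}

#' Write a recording to an EDF file
#'
#' Standard 16-bit EDF: per-channel physical range taken from the data,
#' one-second data records when the length divides evenly by `fs`,
#' otherwise a single record spanning the whole signal. Headers use fixed
#' date/time placeholders so output is a pure function of the data
#' (write/read/write is byte-stable).
#'
#' @param rec A [recording()].
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_edf <- function(rec, path) {
  stopifnot(inherits(rec, "recording"))
  sig <- rec$signals
  if (nrow(sig) == 0L) stop("empty channel list", call. = FALSE)
  if (!all(is.finite(sig))) {
    stop("signals must be finite to write EDF", call. = FALSE)
  }
  n <- ncol(sig)
  ns <- nrow(sig)
  if (n %% rec$fs == 0 && n > 0) {
    n_rec <- as.integer(n / rec$fs)
    rec_dur <- 1
    spr <- as.integer(rec$fs)
  } else {
    n_rec <- 1L
    rec_dur <- n / rec$fs
    spr <- n
  }

  pmin_ <- numeric(ns); pmax_ <- numeric(ns)
  for (i in seq_len(ns)) {
    lo <- min(sig[i, ]); hi <- max(sig[i, ])
    if (hi <= lo) hi <- lo + 1
    # store the parsed values so the digital scaling matches the header
    pmin_[i] <- as.numeric(format_edf_num(lo))
    pmax_[i] <- as.numeric(format_edf_num(hi))
    if (pmax_[i] <= pmin_[i]) pmax_[i] <- pmin_[i] + 1
  }

  con <- file(path, "wb")
  on.exit(close(con))
  hdr <- paste0(
    pad_field("0", 8),
    pad_field("X X X X", 80),
    pad_field("Startdate X X X X", 80),
    pad_field("01.01.00", 8),
    pad_field("00.00.00", 8),
    pad_field(EDF_HEADER_BYTES + ns * EDF_PER_SIGNAL_BYTES, 8),
    pad_field("", 44),
    pad_field(n_rec, 8),
    pad_field(format_edf_num(rec_dur), 8),
    pad_field(ns, 4)
  )
  writeChar(hdr, con, eos = NULL)
  writeChar(paste0(vapply(rec$channel_labels, pad_field, "", width = 16),
                   collapse = ""), con, eos = NULL)
  writeChar(paste0(rep(pad_field("", 80), ns), collapse = ""), con, eos = NULL)
  writeChar(paste0(rep(pad_field("uV", 8), ns), collapse = ""), con, eos = NULL)
  writeChar(paste0(vapply(pmin_, function(v) pad_field(format_edf_num(v), 8),
                          ""), collapse = ""), con, eos = NULL)
  writeChar(paste0(vapply(pmax_, function(v) pad_field(format_edf_num(v), 8),
                          ""), collapse = ""), con, eos = NULL)
  writeChar(paste0(rep(pad_field(EDF_DIG_MIN, 8), ns), collapse = ""),
            con, eos = NULL)
  writeChar(paste0(rep(pad_field(EDF_DIG_MAX, 8), ns), collapse = ""),
            con, eos = NULL)
  writeChar(paste0(rep(pad_field("", 80), ns), collapse = ""), con, eos = NULL)
  writeChar(paste0(rep(pad_field(spr, 8), ns), collapse = ""), con, eos = NULL)
  writeChar(paste0(rep(pad_field("", 32), ns), collapse = ""), con, eos = NULL)

  drange <- EDF_DIG_MAX - EDF_DIG_MIN
  dig <- matrix(0L, nrow = ns, ncol = n)
  for (i in seq_len(ns)) {
    d <- round((sig[i, ] - pmin_[i]) / (pmax_[i] - pmin_[i]) * drange +
               EDF_DIG_MIN)
    dig[i, ] <- as.integer(pmin(pmax(d, EDF_DIG_MIN), EDF_DIG_MAX))
  }
  for (r in seq_len(n_rec)) {
    idx <- ((r - 1L) * spr + 1L):(r * spr)
    for (i in seq_len(ns)) {
      writeBin(dig[i, idx], con, size = 2L, endian = "little")
    }
  }
  invisible(path)
}

read_ascii <- function(raw_vec, offset, width) {
  trimws(rawToChar(raw_vec[(offset + 1L):(offset + width)]))
}

#' Read an EDF file
#'
#' Returns signals in physical units with labels preserved in file order.
#'
#' @param path Path to an EDF file.
#' @param require_labels Optional character vector of channel labels that
#'   must be present; a montage error listing the missing labels is raised
#'   otherwise.
#' @return A [recording()].
#' @export
load_recording <- function(path, require_labels = NULL) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  size <- file.info(path)$size
  if (size < EDF_HEADER_BYTES) {
    stop("EDF format error: truncated header", call. = FALSE)
  }
  raw_all <- readBin(path, "raw", n = size)
  get <- function(off, w) read_ascii(raw_all, off, w)
  ns <- suppressWarnings(as.integer(get(252L, 4L)))
  n_rec <- suppressWarnings(as.integer(get(236L, 8L)))
  rec_dur <- suppressWarnings(as.numeric(get(244L, 8L)))
  hdr_bytes <- suppressWarnings(as.integer(get(184L, 8L)))
  if (anyNA(c(ns, n_rec, rec_dur, hdr_bytes)) || ns < 1L || n_rec < 1L ||
      hdr_bytes != EDF_HEADER_BYTES + ns * EDF_PER_SIGNAL_BYTES) {
    stop("EDF format error: malformed header", call. = FALSE)
  }
  if (size < hdr_bytes) {
    stop("EDF format error: truncated header", call. = FALSE)
  }
  sig_field <- function(idx, width, pos) {
    # pos = 0:labels,1:transducer,2:dim,3:pmin,4:pmax,5:dmin,6:dmax,7:prefilt,8:spr
    offsets <- c(0L, 16L, 96L, 104L, 112L, 120L, 128L, 136L, 216L)
    base <- EDF_HEADER_BYTES + offsets[pos + 1L] * ns
    read_ascii(raw_all, base + (idx - 1L) * width, width)
  }
  labels <- vapply(seq_len(ns), function(i) sig_field(i, 16L, 0L), "")
  pmin_ <- vapply(seq_len(ns), function(i)
    as.numeric(sig_field(i, 8L, 3L)), 0)
  pmax_ <- vapply(seq_len(ns), function(i)
    as.numeric(sig_field(i, 8L, 4L)), 0)
  dmin_ <- vapply(seq_len(ns), function(i)
    as.numeric(sig_field(i, 8L, 5L)), 0)
  dmax_ <- vapply(seq_len(ns), function(i)
    as.numeric(sig_field(i, 8L, 6L)), 0)
  spr <- vapply(seq_len(ns), function(i)
    suppressWarnings(as.integer(sig_field(i, 8L, 8L))), 0L)
  if (anyNA(c(pmin_, pmax_, dmin_, dmax_, spr)) || any(spr < 1L) ||
      any(dmax_ <= dmin_)) {
    stop("EDF format error: malformed signal headers", call. = FALSE)
  }
  expected <- hdr_bytes + n_rec * sum(spr) * 2
  if (size < expected) {
    stop("EDF format error: truncated data section", call. = FALSE)
  }
  dig <- readBin(raw_all[(hdr_bytes + 1L):expected], "integer",
                 n = n_rec * sum(spr), size = 2L, signed = TRUE,
                 endian = "little")
  signals <- matrix(0, nrow = ns, ncol = n_rec * spr[1L])
  # all signals in this package share one sampling rate
  if (length(unique(spr)) != 1L) {
    stop("EDF format error: heterogeneous sampling rates unsupported",
         call. = FALSE)
  }
  pos <- 0L
  for (r in seq_len(n_rec)) {
    for (i in seq_len(ns)) {
      seg <- dig[(pos + 1L):(pos + spr[i])]
      pos <- pos + spr[i]
      phys <- (seg - dmin_[i]) * (pmax_[i] - pmin_[i]) /
        (dmax_[i] - dmin_[i]) + pmin_[i]
      signals[i, ((r - 1L) * spr[i] + 1L):(r * spr[i])] <- phys
    }
  }
  fs <- spr[1L] / rec_dur
  if (!is.null(require_labels)) {
    missing <- setdiff(require_labels, labels)
    if (length(missing) > 0) {
      stop("montage error: missing channel labels: ",
           paste(missing, collapse = ", "), call. = FALSE)
    }
  }
  recording(signals, fs, labels)
}

#' Integer-ratio downsampling with anti-alias filtering
#'
#' Applies a zero-phase windowed-sinc low-pass filter with cutoff at
#' `0.45 * fs_out` (reflection-padded convolution with a symmetric FIR, so
#' no phase shift), then keeps every `fs_in/fs_out`-th sample.
#'
#' @param signal Numeric vector.
#' @param fs_in,fs_out Input/output sampling rates; `fs_in` must be an
#'   integer multiple of `fs_out`.
#' @param n_taps Length of the FIR filter (odd).
#' @return Numeric vector of length `floor(length(signal) * fs_out / fs_in)`.
#' @export
downsample <- function(signal, fs_in, fs_out, n_taps = 101L) {
  r <- fs_in / fs_out
  if (abs(r - round(r)) > 1e-9 || r < 1) {
    stop("fs_in must be an integer multiple of fs_out", call. = FALSE)
  }
  r <- as.integer(round(r))
  if (r == 1L) return(signal)
  fc <- 0.45 * fs_out / fs_in          # normalized cutoff (cycles/sample)
  m <- (n_taps - 1L) / 2L
  k <- -m:m
  h <- 2 * fc * sinc(2 * fc * k) * (0.54 + 0.46 * cos(pi * k / m))
  h <- h / sum(h)
  n <- length(signal)
  pad <- min(m, n - 1L)
  ext <- c(rev(signal[2:(pad + 1L)]), signal, rev(signal[(n - pad):(n - 1L)]))
  y <- stats::filter(ext, h, sides = 2)
  y <- as.numeric(y[(pad + 1L):(pad + n)])
  out_len <- floor(n * fs_out / fs_in)
  y[(seq_len(out_len) - 1L) * r + 1L]
}

sinc <- function(x) ifelse(x == 0, 1, sin(pi * x) / (pi * x))

#' Seizure intervals
#'
#' Half-open intervals `[start_s, end_s)` in seconds from recording start.
#'
#' @param start_s,end_s Numeric vectors of equal length.
#' @return data.frame with columns `start_s`, `end_s`.
#' @export
seizure_intervals <- function(start_s, end_s) {
  stopifnot(length(start_s) == length(end_s))
  if (any(start_s < 0) || any(end_s <= start_s)) {
    stop("intervals must satisfy 0 <= start_s < end_s", call. = FALSE)
  }
  data.frame(start_s = as.numeric(start_s), end_s = as.numeric(end_s))
}

#' Read / write seizure intervals as a two-column CSV
#'
#' @param path CSV file with columns `start_s`, `end_s`.
#' @return For `read_intervals`, a data.frame of intervals.
#' @export
read_intervals <- function(path) {
  df <- read.csv(path)
  if (!all(c("start_s", "end_s") %in% names(df))) {
    stop("intervals CSV must have columns start_s,end_s", call. = FALSE)
  }
  seizure_intervals(df$start_s, df$end_s)
}

#' @rdname read_intervals
#' @param intervals data.frame of intervals.
#' @export
write_intervals <- function(intervals, path) {
  write.csv(intervals[, c("start_s", "end_s")], path, row.names = FALSE)
  invisible(path)
}

#' Cut balanced seizure / seizure-free epochs from a recording
#'
#' Seizure epochs are the non-overlapping `epoch_s`-second windows lying
#' fully inside the annotated intervals; an equal number of seizure-free
#' epochs is drawn (seeded, uniformly without replacement) from candidate
#' windows at `epoch_s` stride lying fully outside all intervals, optionally
#' keeping `margin_s` seconds clear of every interval.
#'
#' @param rec A [recording()].
#' @param intervals data.frame from [seizure_intervals()].
#' @param epoch_s Epoch length in seconds (`epoch_s * fs` must be integer).
#' @param seed Integer seed for the control-window draw.
#' @param margin_s Exclusion margin around intervals for the control class.
#' @return An [epoch_set()] (label 1 = seizure).
#' @export
epoch_and_label <- function(rec, intervals, epoch_s = 6, seed = 1,
                            margin_s = 0) {
  stopifnot(inherits(rec, "recording"))
  n <- ncol(rec$signals)
  dur <- n / rec$fs
  len <- epoch_s * rec$fs
  if (abs(len - round(len)) > 1e-9) {
    stop("epoch_s * fs must be an integer number of samples", call. = FALSE)
  }
  len <- as.integer(round(len))
  if (nrow(intervals) == 0) {
    stop("empty-class error: no seizure intervals provided", call. = FALSE)
  }
  if (any(intervals$start_s < 0) || any(intervals$end_s > dur + 1e-9)) {
    stop("intervals must lie within the recording", call. = FALSE)
  }
  seiz_starts <- unlist(lapply(seq_len(nrow(intervals)), function(i) {
    a <- intervals$start_s[i]; b <- intervals$end_s[i]
    k <- floor((b - a) / epoch_s + 1e-9)
    if (k < 1) return(numeric(0))
    a + (seq_len(k) - 1) * epoch_s
  }))
  if (length(seiz_starts) == 0) {
    stop("empty-class error: no complete seizure window fits any interval",
         call. = FALSE)
  }
  # complement segments, with exclusion margin
  lo <- pmax(intervals$start_s - margin_s, 0)
  hi <- pmin(intervals$end_s + margin_s, dur)
  o <- order(lo)
  lo <- lo[o]; hi <- hi[o]
  free <- list(); cur <- 0
  for (i in seq_along(lo)) {
    if (lo[i] > cur) free[[length(free) + 1L]] <- c(cur, lo[i])
    cur <- max(cur, hi[i])
  }
  if (cur < dur) free[[length(free) + 1L]] <- c(cur, dur)
  free_starts <- unlist(lapply(free, function(seg) {
    k <- floor((seg[2] - seg[1]) / epoch_s + 1e-9)
    if (k < 1) return(numeric(0))
    seg[1] + (seq_len(k) - 1) * epoch_s
  }))
  m <- length(seiz_starts)
  if (length(free_starts) < m) {
    stop("empty-class error: not enough seizure-free windows to balance",
         call. = FALSE)
  }
  picked <- with_seed(seed, sort(sample(free_starts, m)))
  extract <- function(starts) {
    arr <- array(0, dim = c(nrow(rec$signals), len, length(starts)))
    for (j in seq_along(starts)) {
      i0 <- as.integer(round(starts[j] * rec$fs))
      arr[, , j] <- rec$signals[, (i0 + 1L):(i0 + len), drop = FALSE]
    }
    arr
  }
  data <- array(0, dim = c(nrow(rec$signals), len, 2L * m))
  data[, , seq_len(m)] <- extract(picked)
  data[, , m + seq_len(m)] <- extract(seiz_starts)
  epoch_set(data, c(rep(0L, m), rep(1L, m)), rec$fs, rec$channel_labels)
}

#' Export / import an epoch set as EDF + labels CSV
#'
#' Serializes an [epoch_set()] as a directory holding one EDF per class
#' (epochs concatenated in order) plus a `labels.csv` with the epoch length,
#' so the pipeline is format-agnostic downstream.
#'
#' @param es An [epoch_set()].
#' @param dir Output directory (created if needed).
#' @return For `import_epochs`, the reconstructed [epoch_set()].
#' @export
export_epochs <- function(es, dir) {
  stopifnot(inherits(es, "epoch_set"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  len <- dim(es$data)[2]
  for (cls in c(0L, 1L)) {
    idx <- which(es$labels == cls)
    if (length(idx) == 0) next
    flat <- matrix(es$data[, , idx, drop = FALSE],
                   nrow = dim(es$data)[1])
    write_edf(recording(flat, es$fs, es$channel_labels),
              file.path(dir, sprintf("class%d.edf", cls)))
  }
  write.csv(data.frame(class = c(0L, 1L),
                       n_epochs = c(sum(es$labels == 0L),
                                    sum(es$labels == 1L)),
                       epoch_samples = len, fs = es$fs),
            file.path(dir, "labels.csv"), row.names = FALSE)
  invisible(dir)
}

#' @rdname export_epochs
#' @export
import_epochs <- function(dir) {
  meta <- read.csv(file.path(dir, "labels.csv"))
  len <- meta$epoch_samples[1]
  parts <- list(); labs <- integer(0)
  chl <- NULL; fs <- meta$fs[1]
  for (i in seq_len(nrow(meta))) {
    if (meta$n_epochs[i] == 0) next
    rec <- load_recording(file.path(dir, sprintf("class%d.edf",
                                                 meta$class[i])))
    chl <- rec$channel_labels
    arr <- array(rec$signals, dim = c(nrow(rec$signals), len,
                                      meta$n_epochs[i]))
    parts[[length(parts) + 1L]] <- arr
    labs <- c(labs, rep(meta$class[i], meta$n_epochs[i]))
  }
  data <- array(0, dim = c(dim(parts[[1]])[1], len, length(labs)))
  k <- 0L
  for (p in parts) {
    data[, , k + seq_len(dim(p)[3])] <- p
    k <- k + dim(p)[3]
  }
  epoch_set(data, labs, fs, chl)
}
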