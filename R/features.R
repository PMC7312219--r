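# Per-sub-band features: two log-energies (instantaneous, Teager) and two
# fractal dimensions (Higuchi, Petrosian), assembled into a per-epoch
# feature table with a channel-block column index.

FEATURE_NAMES <- c("instE", "teagerE", "higuchiFD", "petrosianFD")
ENERGY_FLOOR <- 1e-12   # silent bands: both energies are floored at log10(eps)

band_samples <- function(x) {
  if (inherits(x, "subband")) x$samples else as.numeric(x)
}

#' Instantaneous (log) energy
#'
#' \eqn{\log_{10}\left(\frac{1}{N}\sum_r w(r)^2\right)}; the mean square is
#' floored at `1e-12` so silent bands give -12 instead of `-Inf`.
#'
#' @param band A [subband()] or numeric vector.
#' @return Scalar.
#' @export
instantaneous_energy <- function(band) {
  x <- band_samples(band)
  stopifnot(length(x) >= 1L)
  log10(max(mean(x^2), ENERGY_FLOOR))
}

#' Teager (log) energy
#'
#' Mean of the discrete Teager-Kaiser operator
#' \eqn{|w(r)^2 - w(r-1)w(r+1)|} over the interior samples
#' (r = 2..N-1; the boundary terms lack a neighbour), divided by N, in
#' log base 10. Floored at `1e-12` for constant sequences, where the
#' operator vanishes identically.
#'
#' @param band A [subband()] or numeric vector of length >= 3.
#' @return Scalar.
#' @export
teager_energy <- function(band) {
  x <- band_samples(band)
  n <- length(x)
  if (n < 3L) stop("Teager energy needs at least 3 samples", call. = FALSE)
  s <- sum(abs(x[2:(n - 1L)]^2 - x[1:(n - 2L)] * x[3:n]))
  log10(max(s / n, ENERGY_FLOOR))
}

#' Higuchi fractal dimension
#'
#' Estimates the fractal dimension of a series directly in the time domain
#' from mean curve lengths \eqn{L(k)} at interval sizes `k = 1..k_max`:
#' for each offset m, \eqn{L_m(k)} is the normalized absolute increment sum
#' of the subsampled series, \eqn{L(k)} is the mean over m, and the FD is
#' the slope of `ln L(k)` against `ln(1/k)`. Smooth curves approach 1,
#' white noise approaches 2. A constant signal has zero curve length and
#' returns the documented sentinel 0 with a warning.
#'
#' @param signal Numeric vector with `length(signal) > 2 * k_max`.
#' @param k_max Maximum interval size (default 10, conventional for
#'   epochs of a few hundred samples).
#' @return Scalar FD estimate.
#' @export
higuchi_fd <- function(signal, k_max = 10) {
  x <- band_samples(signal)
  n <- length(x)
  k_max <- assert_count(k_max, "k_max", min = 2L)
  if (k_max >= n / 2 || n <= 2 * k_max) {
    stop("k_max out of range: need 2 <= k_max < N/2", call. = FALSE)
  }
  lk <- numeric(k_max)
  for (k in seq_len(k_max)) {
    lm <- numeric(k)
    for (m in seq_len(k)) {
      nm <- floor((n - m) / k)
      if (nm < 1L) { lm[m] <- 0; next }
      idx <- m + (0:nm) * k
      lm[m] <- sum(abs(diff(x[idx]))) * (n - 1) / (nm * k) / k
    }
    lk[k] <- mean(lm)
  }
  if (any(lk <= 0)) {
    warning("curve length is zero (constant signal); returning FD = 0")
    return(0)
  }
  lx <- log(1 / seq_len(k_max))
  ly <- log(lk)
  abs(sum((lx - mean(lx)) * (ly - mean(ly))) / sum((lx - mean(lx))^2))
}

#' Higuchi curve-length profile at one interval size
#'
#' Exposes the per-offset lengths \eqn{L_m(k)} and their mean \eqn{L(k)}
#' used inside [higuchi_fd()]; mainly for inspection and testing.
#'
#' @param signal Numeric vector.
#' @param k Interval size.
#' @return List with `k`, `L_m_values`, `L`.
#' @export
curve_length_profile <- function(signal, k) {
  x <- band_samples(signal)
  n <- length(x)
  k <- assert_count(k, "k")
  lm <- numeric(k)
  for (m in seq_len(k)) {
    nm <- floor((n - m) / k)
    if (nm < 1L) { lm[m] <- 0; next }
    idx <- m + (0:nm) * k
    lm[m] <- sum(abs(diff(x[idx]))) * (n - 1) / (nm * k) / k
  }
  list(k = k, L_m_values = lm, L = mean(lm))
}

#' Petrosian fractal dimension
#'
#' The series is binarized by the sign of its first difference (zero
#' differences inherit the previous sign) and \eqn{N_\nabla} counts the
#' sign changes between consecutive differences. Then
#' \deqn{FD = \log_{10} n / (\log_{10} n + \log_{10}(n / (n + 0.4 N_\nabla)))}
#' with n the sequence length. A monotone sequence gives exactly 1.
#'
#' @param signal Numeric vector of length >= 3.
#' @return Scalar in `[1, ~1.1]`, increasing with the sign-change count.
#' @export
petrosian_fd <- function(signal) {
  x <- band_samples(signal)
  n <- length(x)
  if (n < 3L) stop("Petrosian FD needs at least 3 samples", call. = FALSE)
  s <- sign(diff(x))
  last <- 1
  for (i in seq_along(s)) {
    if (s[i] == 0) s[i] <- last else last <- s[i]
  }
  n_delta <- sum(s[-1] != s[-length(s)])
  log10(n) / (log10(n) + log10(n / (n + 0.4 * n_delta)))
}

features_of_band <- function(band, k_max = 10) {
  x <- band_samples(band)
  n <- length(x)
  if (all(x == x[1])) {
    # degenerate (silent/constant) band: documented floors and sentinels
    return(c(instantaneous_energy(x), teager_energy(x), 0, petrosian_fd(x)))
  }
  km <- max(2L, min(as.integer(k_max), as.integer(floor((n - 1) / 2)) - 1L))
  c(instantaneous_energy(x), teager_energy(x),
    higuchi_fd(x, k_max = km), petrosian_fd(x))
}

#' Per-channel feature vector
#'
#' Decomposes one channel's epoch and computes the four features per
#' sub-band: 2 selected IMFs x 4 = 8 features for EMD, 5 wavelet bands x 4
#' = 20 for DWT. Ordering is fixed: sub-bands first (IMFs by ascending
#' distance to the signal; A4, D4, D3, D2, D1 for DWT), then
#' (instantaneous energy, Teager energy, Higuchi FD, Petrosian FD) within
#' each sub-band. If EMD yields fewer than `n_keep` IMFs the missing
#' blocks are zero-filled so the vector length is constant.
#'
#' @param channel_epoch Numeric vector (one channel, one epoch).
#' @param method `"EMD"` or `"DWT"`.
#' @param fs Sampling rate (annotates DWT bands).
#' @param emd_cfg An [emd_config()].
#' @param k_max Higuchi `k_max`.
#' @param dwt_levels DWT decomposition depth.
#' @return Named numeric vector of length 8 (EMD) or `4 * (dwt_levels+1)`
#'   (DWT).
#' @export
channel_features <- function(channel_epoch, method = c("DWT", "EMD"),
                             fs = 128, emd_cfg = emd_config(), k_max = 10,
                             dwt_levels = 4) {
  method <- match.arg(method)
  x <- as.numeric(channel_epoch)
  if (method == "DWT") {
    bands <- dwt_decompose(x, levels = dwt_levels, fs = fs)
    out <- unlist(lapply(bands, features_of_band, k_max = k_max))
    names(out) <- as.vector(t(outer(
      vapply(bands, function(b) b$origin, ""), FEATURE_NAMES, paste,
      sep = "__")))
  } else {
    dec <- sift_emd(x, emd_cfg)
    sel <- select_imfs(x, dec$imfs, n_keep = emd_cfg$n_keep,
                       p = emd_cfg$minkowski_p)
    out <- numeric(0)
    for (slot in seq_len(emd_cfg$n_keep)) {
      if (slot <= length(sel)) {
        out <- c(out, features_of_band(dec$imfs[[sel[slot]]], k_max = k_max))
      } else {
        out <- c(out, rep(0, 4L))   # degenerate epoch: zero-filled block
      }
    }
    names(out) <- as.vector(t(outer(
      paste0("IMF", seq_len(emd_cfg$n_keep)), FEATURE_NAMES, paste,
      sep = "__")))
  }
  out
}

#' Build a feature table from an epoch set
#'
#' One row per epoch; columns are per-channel blocks in montage order,
#' each block holding the [channel_features()] vector. The block index
#' maps channels to column ranges so channel subsets slice exactly their
#' own columns.
#'
#' @param epochs An [epoch_set()].
#' @inheritParams channel_features
#' @return Object of class `feature_table`: list with `matrix`
#'   (instances x C*F), `labels`, `block_index`, `F`, `method`,
#'   `channel_labels`.
#' @export
build_feature_table <- function(epochs, method = c("DWT", "EMD"),
                                emd_cfg = emd_config(), k_max = 10,
                                dwt_levels = 4) {
  stopifnot(inherits(epochs, "epoch_set"))
  method <- match.arg(method)
  d <- dim(epochs$data)
  C <- d[1]; n_ep <- d[3]
  first <- channel_features(epochs$data[1, , 1], method, fs = epochs$fs,
                            emd_cfg = emd_cfg, k_max = k_max,
                            dwt_levels = dwt_levels)
  F_per <- length(first)
  mat <- matrix(0, nrow = n_ep, ncol = C * F_per)
  colnames(mat) <- as.vector(vapply(epochs$channel_labels, function(ch) {
    paste(ch, names(first), sep = "__")
  }, character(F_per)))
  for (e in seq_len(n_ep)) {
    for (ch in seq_len(C)) {
      mat[e, ((ch - 1L) * F_per + 1L):(ch * F_per)] <-
        channel_features(epochs$data[ch, , e], method, fs = epochs$fs,
                         emd_cfg = emd_cfg, k_max = k_max,
                         dwt_levels = dwt_levels)
    }
  }
  block_index <- lapply(seq_len(C), function(ch) {
    ((ch - 1L) * F_per + 1L):(ch * F_per)
  })
  names(block_index) <- epochs$channel_labels
  structure(list(matrix = mat, labels = epochs$labels,
                 block_index = block_index, F = F_per, method = method,
                 channel_labels = epochs$channel_labels),
            class = "feature_table")
}

#' @export
print.feature_table <- function(x, ...) {
  cat(sprintf(
    "<feature_table> %d instances x %d columns (%d channels x %d %s features)\n",
    nrow(x$matrix), ncol(x$matrix), length(x$block_index), x$F, x$method))
  invisible(x)
}

#' Number of channels in a feature table
#' @param table A `feature_table`.
#' @return Integer channel count.
#' @export
n_channels <- function(table) {
  stopifnot(inherits(table, "feature_table"))
  length(table$block_index)
}

# Columns belonging to a channel subset (indices or labels), in montage order.
subset_columns <- function(table, subset) {
  if (is.character(subset)) {
    subset <- match(subset, table$channel_labels)
  }
  subset <- sort(unique(as.integer(subset)))
  if (length(subset) == 0) stop("empty channel subset", call. = FALSE)
  if (min(subset) < 1L || max(subset) > length(table$block_index)) {
    stop("subset outside montage", call. = FALSE)
  }
  unname(unlist(table$block_index[subset]))
}

#' Serialize / read a feature table as CSV
#'
#' Header row `label,<chan>__<band>__<feature>,...`; values written at 17
#' significant digits so the round trip is lossless.
#'
#' @param table A `feature_table`.
#' @param path CSV path.
#' @return For `read_feature_table`, the reconstructed `feature_table`.
#' @export
write_feature_table <- function(table, path) {
  stopifnot(inherits(table, "feature_table"))
  df <- data.frame(label = table$labels, check.names = FALSE)
  m <- as.data.frame(table$matrix, check.names = FALSE)
  out <- cbind(df, m)
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(paste(c("label", colnames(table$matrix)), collapse = ","), con)
  body <- apply(out, 1L, function(row) {
    paste(c(format(as.integer(row[1])),
            formatC(as.numeric(row[-1]), digits = 17, format = "g")),
          collapse = ",")
  })
  writeLines(body, con)
  invisible(path)
}

#' @rdname write_feature_table
#' @param method,F Method tag and per-channel feature count; inferred from
#'   the header when omitted.
#' @export
read_feature_table <- function(path, method = NULL, F = NULL) {
  df <- read.csv(path, check.names = FALSE)
  labels <- as.integer(df$label)
  mat <- as.matrix(df[, -1, drop = FALSE])
  cols <- colnames(mat)
  chans <- unique(vapply(strsplit(cols, "__", fixed = TRUE),
                         `[`, "", 1L))
  F_per <- length(cols) / length(chans)
  if (is.null(F)) F <- as.integer(F_per)
  if (is.null(method)) {
    method <- if (grepl("__IMF", paste0("__", cols[1]), fixed = TRUE) ||
                  grepl("IMF", cols[1], fixed = TRUE)) "EMD" else "DWT"
  }
  block_index <- lapply(seq_along(chans), function(ch) {
    ((ch - 1L) * F + 1L):(ch * F)
  })
  names(block_index) <- chans
  structure(list(matrix = mat, labels = labels, block_index = block_index,
                 F = F, method = method, channel_labels = chans),
            class = "feature_table")
}
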