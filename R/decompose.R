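# Sub-band decomposition: empirical mode decomposition (sifting with cubic
# spline envelopes) and a 4-level biorthogonal-2.2 discrete wavelet filter
# bank. Both return lists of `subband` objects consumed by the feature stage.

#' An oscillatory sub-band of one channel's epoch
#'
#' @param samples Numeric vector of sub-band samples/coefficients.
#' @param origin Tag: `"IMF<k>"` or a wavelet level (`"A4"`, `"D4"`, ...).
#' @param nominal_band Optional `c(lo, hi)` Hz range (DWT bands only).
#' @return Object of class `subband`.
#' @export
subband <- function(samples, origin, nominal_band = NULL) {
  structure(list(samples = as.numeric(samples), origin = origin,
                 nominal_band = nominal_band),
            class = "subband")
}

#' @export
print.subband <- function(x, ...) {
  band <- if (is.null(x$nominal_band)) "" else
    sprintf(" (%g-%g Hz)", x$nominal_band[1], x$nominal_band[2])
  cat(sprintf("<subband %s> %d samples%s\n", x$origin,
              length(x$samples), band))
  invisible(x)
}

#' EMD configuration
#'
#' @param max_imfs Maximum number of IMFs extracted.
#' @param max_sift_iters Sifting iterations per IMF before forcing a stop.
#' @param sd_threshold Stop sifting when the normalized squared change
#'   between consecutive sift iterates falls below this (classical SD
#'   criterion; 0.2 is the conventional choice).
#' @param n_keep Number of IMFs retained downstream (closest to the signal).
#' @param minkowski_p Order of the Minkowski distance used for IMF
#'   selection; 2 (Euclidean) by default.
#' @return Object of class `emd_config`.
#' @export
emd_config <- function(max_imfs = 10, max_sift_iters = 50,
                       sd_threshold = 0.2, n_keep = 2, minkowski_p = 2) {
  stopifnot(sd_threshold > 0, n_keep >= 1, minkowski_p >= 1)
  structure(list(max_imfs = assert_count(max_imfs, "max_imfs"),
                 max_sift_iters = assert_count(max_sift_iters,
                                               "max_sift_iters"),
                 sd_threshold = sd_threshold,
                 n_keep = assert_count(n_keep, "n_keep"),
                 minkowski_p = minkowski_p),
            class = "emd_config")
}

# Indices of local maxima and minima; plateaus collapse to one extremum.
find_extrema <- function(x) {
  d <- diff(x)
  s <- sign(d)
  nz <- which(s != 0)
  if (length(nz) == 0) return(list(maxima = integer(0), minima = integer(0)))
  # carry the previous non-zero slope through plateaus
  s_filled <- s
  last <- s[nz[1]]
  for (i in seq_along(s_filled)) {
    if (s_filled[i] == 0) s_filled[i] <- last else last <- s_filled[i]
  }
  ds <- diff(s_filled)
  list(maxima = which(ds < 0) + 1L, minima = which(ds > 0) + 1L)
}

# Cubic-spline envelope through extrema with 2 extrema mirrored at each end
# (mitigates end effects). Returns the envelope evaluated at 1..n.
spline_envelope <- function(x, ext_idx, n) {
  k <- length(ext_idx)
  t <- ext_idx
  v <- x[ext_idx]
  nm <- min(2L, k)
  left_t <- 2 - t[seq_len(nm)]
  left_v <- v[seq_len(nm)]
  right_t <- 2 * n - t[k - seq_len(nm) + 1L]
  right_v <- v[k - seq_len(nm) + 1L]
  tt <- c(rev(left_t), t, rev(right_t))
  vv <- c(rev(left_v), v, rev(right_v))
  keep <- !duplicated(tt)
  spline(tt[keep], vv[keep], xout = seq_len(n), method = "fmm")$y
}

sift_one_imf <- function(x, config) {
  h <- x
  n <- length(x)
  for (it in seq_len(config$max_sift_iters)) {
    ext <- find_extrema(h)
    if (length(ext$maxima) < 2L || length(ext$minima) < 2L) break
    upper <- spline_envelope(h, ext$maxima, n)
    lower <- spline_envelope(h, ext$minima, n)
    m <- (upper + lower) / 2
    h_new <- h - m
    denom <- sum(h^2)
    sd_crit <- if (denom > 0) sum((h - h_new)^2) / denom else 0
    h <- h_new
    if (sd_crit < config$sd_threshold) break
  }
  h
}

#' Empirical mode decomposition by sifting
#'
#' Decomposes a signal into intrinsic mode functions (IMFs) by iterative
#' envelope-mean subtraction. Sifting of each IMF stops on the classical SD
#' criterion (`sd_threshold`); decomposition stops when the residue has
#' fewer than 3 extrema or `max_imfs` is reached. The IMFs plus residue
#' reconstruct the input exactly (by construction).
#'
#' @param signal Numeric vector (length >= 8).
#' @param config An [emd_config()].
#' @return List with `imfs` (list of [subband()] tagged `IMF1..`) and
#'   `residue` (numeric vector). A monotonic input yields zero IMFs with
#'   `residue == signal`.
#' @export
sift_emd <- function(signal, config = emd_config()) {
  stopifnot(is.numeric(signal))
  if (length(signal) < 8L) stop("signal too short for EMD", call. = FALSE)
  residue <- signal
  imfs <- list()
  while (length(imfs) < config$max_imfs) {
    ext <- find_extrema(residue)
    if (length(ext$maxima) + length(ext$minima) < 3L ||
        length(ext$maxima) < 2L || length(ext$minima) < 2L) break
    imf <- sift_one_imf(residue, config)
    imfs[[length(imfs) + 1L]] <- subband(imf,
                                         sprintf("IMF%d", length(imfs) + 1L))
    residue <- residue - imf
  }
  list(imfs = imfs, residue = residue)
}

#' Select the IMFs closest to the original signal
#'
#' Redundant IMFs produced by sifting show maximal Minkowski (Euclidean)
#' distance to the original signal; the retained IMFs are the `n_keep`
#' closest ones. Ties break toward the lower IMF index.
#'
#' @param signal Original signal.
#' @param imfs List of [subband()] IMFs from [sift_emd()].
#' @param n_keep How many indices to return (fewer if fewer IMFs exist).
#' @param p Minkowski order (2 = Euclidean).
#' @return Integer indices into `imfs`, ascending by distance.
#' @export
select_imfs <- function(signal, imfs, n_keep = 2, p = 2) {
  if (length(imfs) == 0) return(integer(0))
  d <- vapply(imfs, function(b) {
    sum(abs(b$samples - signal)^p)^(1 / p)
  }, 0)
  ord <- order(d)                       # stable: ties keep lower index first
  head(ord, n_keep)
}

# Biorthogonal 2.2 analysis filters (CDF spline construction):
# lowpass  sqrt(2) * [0, -1/8, 1/4, 3/4, 1/4, -1/8]
# highpass sqrt(2) * [0,  1/4, -1/2, 1/4, 0, 0]
bior22_dec_lo <- sqrt(2) * c(0, -1 / 8, 1 / 4, 3 / 4, 1 / 4, -1 / 8)
bior22_dec_hi <- sqrt(2) * c(0, 1 / 4, -1 / 2, 1 / 4, 0, 0)

# One analysis step: half-sample symmetric extension, correlate with the
# filter, keep every second sample. Output length floor((n + L - 1) / 2).
dwt_step <- function(x, h) {
  L <- length(h)
  pad <- L - 1L
  n <- length(x)
  ext <- c(x[pad:1], x, x[n:(n - pad + 1L)])
  m <- n + pad
  out <- numeric(m)
  for (j in seq_len(L)) {
    out <- out + h[j] * ext[j:(j + m - 1L)]
  }
  out[seq(2L, m, by = 2L)]
}

#' Four-level discrete wavelet decomposition (biorthogonal 2.2)
#'
#' Cascaded half-band analysis filters of the bior2.2 wavelet with dyadic
#' decimation and symmetric signal extension. At `fs = 128` Hz and 4
#' levels the sub-bands cover the principal EEG rhythms:
#' A4 0-4, D4 4-8, D3 8-16, D2 16-32, D1 32-64 Hz.
#'
#' @param signal Numeric vector, length >= `2^levels`.
#' @param levels Decomposition depth (default 4).
#' @param fs Sampling rate in Hz, used only to annotate nominal bands.
#' @return List of `levels + 1` [subband()]s in order `A<J>, D<J>, ..., D1`.
#' @export
dwt_decompose <- function(signal, levels = 4, fs = 128) {
  levels <- assert_count(levels, "levels")
  if (length(signal) < 2^levels) {
    stop("signal too short for ", levels, "-level DWT", call. = FALSE)
  }
  a <- as.numeric(signal)
  details <- vector("list", levels)
  for (lev in seq_len(levels)) {
    details[[lev]] <- dwt_step(a, bior22_dec_hi)
    a <- dwt_step(a, bior22_dec_lo)
  }
  bands <- vector("list", levels + 1L)
  bands[[1L]] <- subband(a, sprintf("A%d", levels),
                         nominal_band = c(0, fs / 2^(levels + 1)))
  for (lev in levels:1) {
    bands[[levels - lev + 2L]] <- subband(
      details[[lev]], sprintf("D%d", lev),
      nominal_band = c(fs / 2^(lev + 1), fs / 2^lev))
  }
  bands
}
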