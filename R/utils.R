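# Internal helpers shared across modules.

# Evaluate `code` under a fixed RNG seed, restoring the caller's RNG state.
with_seed <- function(seed, code) {
  stopifnot(is.numeric(seed), length(seed) == 1L, is.finite(seed))
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    get(".Random.seed", envir = globalenv())
  } else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
        rm(".Random.seed", envir = globalenv())
      }
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  })
  set.seed(as.integer(seed))
  force(code)
}

# Derive a bounded substream seed from a base seed and a counter.
# Keeps results reproducible regardless of how many draws earlier epochs used.
substream_seed <- function(seed, counter) {
  (as.double(seed) * 48271 + as.double(counter) * 16807) %% 2147483647
}

assert_count <- function(x, name, min = 1L) {
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x) || x < min ||
      x != round(x)) {
    stop(sprintf("`%s` must be a single integer >= %d", name, min),
         call. = FALSE)
  }
  as.integer(x)
}

assert_number <- function(x, name, min = -Inf) {
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x) || x < min) {
    stop(sprintf("`%s` must be a single finite number >= %g", name, min),
         call. = FALSE)
  }
  as.double(x)
}

# Simple periodogram: two-sided power at Fourier frequencies, returned for
# the positive half-band. Used by tests and the synthetic generator checks.
periodogram_power <- function(x, fs) {
  n <- length(x)
  sp <- abs(fft(x))^2 / n
  k <- seq_len(floor(n / 2))            # positive frequencies, excl. DC
  list(freq = k * fs / n, power = sp[k + 1L])
}
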