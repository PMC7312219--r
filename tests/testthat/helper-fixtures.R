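# Shared fixtures and independent oracles. Everything is generated in code;
# expensive fixtures are memoized for the duration of the test run.

.fixture_env <- new.env(parent = emptyenv())

`%||%` <- function(a, b) if (is.null(a)) b else a

memo <- function(key, expr) {
  if (is.null(.fixture_env[[key]])) .fixture_env[[key]] <- force(expr)
  .fixture_env[[key]]
}

# Small planted dataset: 4 channels, channel 2 informative, 20+20 epochs.
planted_table <- function(seed = 3, method = "DWT", n_per_class = 20,
                          snr = 3) {
  memo(sprintf("planted_%d_%s_%d_%g", seed, method, n_per_class, snr), {
    cfg <- synth_config(n_channels = 4, informative_channels = 2,
                        n_per_class = n_per_class, snr = snr, seed = seed)
    build_feature_table(generate_epochs(cfg), method = method)
  })
}

# A feature table built directly from Gaussian clouds (no EEG involved):
# channel `informative` separated by `delta` between classes.
gaussian_table <- function(n_per_class, C, F_per = 4, informative = 1,
                           delta = 0, seed = 1) {
  n <- 2L * n_per_class
  labels <- rep(c(0L, 1L), each = n_per_class)
  mat <- eegselect:::with_seed(seed, matrix(rnorm(n * C * F_per), nrow = n))
  cols <- ((informative - 1L) * F_per + 1L):(informative * F_per)
  mat[labels == 1L, cols] <- mat[labels == 1L, cols] + delta
  chl <- paste0("CH", seq_len(C))
  colnames(mat) <- as.vector(vapply(chl, function(ch)
    paste0(ch, "__f", seq_len(F_per)), character(F_per)))
  block_index <- lapply(seq_len(C), function(ch)
    ((ch - 1L) * F_per + 1L):(ch * F_per))
  names(block_index) <- chl
  structure(list(matrix = mat, labels = labels, block_index = block_index,
                 F = F_per, method = "DWT", channel_labels = chl),
            class = "feature_table")
}

# Structured deterministic lookup-table fitness over all 2^C - 1 subsets:
# per-channel contributions plus pairwise synergies, as in the real planted
# problem. Enumerable, so the exact Pareto front is computable.
make_lookup_fitness <- function(C, seed) {
  w <- eegselect:::with_seed(seed, runif(C, 0, 0.12))
  syn <- eegselect:::with_seed(seed + 500,
                               matrix(runif(C * C, -0.01, 0.02), C))
  syn <- (syn + t(syn)) / 2
  lut <- numeric(2^C - 1)
  for (m in seq_len(2^C - 1)) {
    ch <- which(bitwAnd(m, 2^(0:(C - 1))) > 0)
    s <- syn[ch, ch, drop = FALSE]
    lut[m] <- min(1, round(0.5 + sum(w[ch]) + sum(s[upper.tri(s)]), 4))
  }
  stub <- function(subset) list(accuracy = lut[sum(2^(subset - 1))])
  attr(stub, "n_channels") <- C
  attr(stub, "lut") <- lut
  stub
}

# Exhaustive Pareto front oracle for a lookup fitness: best accuracy per
# subset size over all subsets, pruned to the non-dominated set.
exhaustive_front <- function(stub) {
  lut <- attr(stub, "lut")
  C <- attr(stub, "n_channels")
  sizes <- vapply(seq_along(lut), function(m)
    sum(bitwAnd(m, 2^(0:(C - 1))) > 0), 0)
  best <- vapply(seq_len(C), function(nn) max(lut[sizes == nn]), 0)
  keep <- vapply(seq_len(C), function(nn)
    best[nn] > max(-Inf, best[seq_len(nn - 1L)]), TRUE)
  data.frame(no = seq_len(C)[keep], acc = best[keep])
}

# O(N^3) brute-force non-dominated sorting oracle: repeatedly peel the set
# of points not dominated by any remaining point.
brute_force_fronts <- function(acc, no) {
  remaining <- seq_along(acc)
  fronts <- list()
  dominates_pair <- function(i, j) {
    (acc[i] >= acc[j] && no[i] <= no[j]) &&
      (acc[i] > acc[j] || no[i] < no[j])
  }
  while (length(remaining) > 0) {
    nd <- remaining[vapply(remaining, function(i) {
      !any(vapply(remaining, function(j) j != i && dominates_pair(j, i),
                  TRUE))
    }, TRUE)]
    fronts[[length(fronts) + 1L]] <- sort(nd)
    remaining <- setdiff(remaining, nd)
  }
  fronts
}

# Band power of one channel in a frequency window, per epoch.
epoch_band_power <- function(es, channel, f_lo, f_hi) {
  vapply(seq_len(dim(es$data)[3]), function(e) {
    pg <- eegselect:::periodogram_power(es$data[channel, , e], es$fs)
    sum(pg$power[pg$freq >= f_lo & pg$freq <= f_hi])
  }, 0)
}
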