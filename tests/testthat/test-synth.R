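# Synthetic EEG generator: determinism, spectral shape, class structure.

test_that("pink_noise is seeded, zero-mean, with ~1/f spectrum", {
  expect_identical(pink_noise(768, 1), pink_noise(768, 1))
  x <- pink_noise(768, 1)
  expect_lt(abs(mean(x)), 3 * sd(x) / sqrt(length(x)))
  # periodogram slope oracle on a long realization
  y <- pink_noise(8192, 7)
  pg <- eegselect:::periodogram_power(y, 1)
  slope <- unname(coef(lm(log(pg$power) ~ log(pg$freq)))[2])
  expect_gt(slope, -1.4)
  expect_lt(slope, -0.6)
  expect_error(pink_noise(1, 1), "n_samples")
})

test_that("spike_wave is normalized, periodic, and 3 Hz dominated", {
  sw <- spike_wave(128, 6, 3)
  expect_length(sw, 768)
  expect_equal(max(abs(sw)), 1)
  # fs/f0 = 32 samples is an integer period: shifting reproduces the wave
  per <- 128 / 4
  sw4 <- spike_wave(128, 6, 4)
  expect_lt(max(abs(sw4[1:(768 - per)] - sw4[(per + 1):768])), 1e-9)
  pg <- eegselect:::periodogram_power(sw, 128)
  i3 <- which.min(abs(pg$freq - 3))
  expect_gt(pg$power[i3] / sum(pg$power), 0.25)
  expect_error(spike_wave(128, 6, 64), "aliasing")
})

test_that("generate_epochs honours shape, balance and determinism", {
  cfg <- synth_config(n_channels = 4, informative_channels = 2,
                      n_per_class = 40, snr = 2, seed = 3)
  es <- generate_epochs(cfg)
  expect_equal(dim(es$data), c(4, 768, 80))
  expect_equal(sum(es$labels == 0L), 40)
  expect_equal(sum(es$labels == 1L), 40)
  es2 <- generate_epochs(cfg)
  expect_identical(es$data, es2$data)
  expect_error(
    synth_config(n_channels = 4, informative_channels = integer(0),
                 snr = 2),
    "informative")
})

test_that("seizure epochs carry excess 2-4 Hz power on informative channels", {
  cfg <- synth_config(n_channels = 4, informative_channels = 2,
                      n_per_class = 40, snr = 3, seed = 3)
  es <- generate_epochs(cfg)
  bp <- epoch_band_power(es, 2, 2, 4)
  seiz <- bp[es$labels == 1L]
  free <- bp[es$labels == 0L]
  expect_gte(mean(seiz > free), 0.95)   # matched pairs share epoch index
})

test_that("non-informative channels are exchangeable between classes", {
  rejections <- 0L
  n_seeds <- 50L
  for (s in seq_len(n_seeds)) {
    cfg <- synth_config(n_channels = 2, informative_channels = 1,
                        n_per_class = 15, snr = 2, seed = 1000 + s)
    es <- generate_epochs(cfg)
    rms <- sqrt(colMeans(es$data[2, , ]^2))
    pv <- suppressWarnings(
      ks.test(rms[es$labels == 0L], rms[es$labels == 1L])$p.value)
    if (pv < 0.05) rejections <- rejections + 1L
  }
  expect_lte(rejections, 0.10 * n_seeds)
})

test_that("downstream accuracy is non-decreasing in snr", {
  accs <- vapply(c(0, 1, 3), function(snr) {
    cfg <- synth_config(n_channels = 2, informative_channels = 1,
                        n_per_class = 20, snr = snr, seed = 7)
    ft <- build_feature_table(generate_epochs(cfg), "DWT")
    evaluate_subset(ft, 1, portfolio_spec(n_trees = 25), k = 10,
                    seed = 1)$accuracy
  }, 0)
  # tolerance: one CV-fold resolution (1 epoch per fold per class)
  expect_true(all(diff(accs) >= -1 / 20))
  expect_gt(accs[3], accs[1])
})

test_that("snr = 0 keeps the informative channel at chance level", {
  cfg <- synth_config(n_channels = 2, informative_channels = 1,
                      n_per_class = 20, snr = 0, seed = 5)
  ft <- build_feature_table(generate_epochs(cfg), "DWT")
  acc <- evaluate_subset(ft, 1, portfolio_spec(n_trees = 25), k = 10,
                         seed = 1)$accuracy
  expect_lt(acc, 0.75)   # best-of-grid selection inflates chance at n = 40
})
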