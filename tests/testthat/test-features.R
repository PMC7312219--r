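# Feature formulas (closed-form unit values), scale behavior, and feature
# table assembly.

test_that("instantaneous energy matches closed forms and floors silence", {
  expect_equal(instantaneous_energy(c(1, 1, 1, 1)), 0)
  expect_equal(instantaneous_energy(c(1, 2, 3)), log10(14 / 3))
  expect_equal(instantaneous_energy(rep(0, 10)), -12)
})

test_that("Teager energy matches hand and closed-form evaluations", {
  expect_equal(teager_energy(c(1, 2, 3, 4)), log10(0.5))
  expect_equal(teager_energy(rep(2, 50)), -12)   # operator vanishes
  r <- 1:768
  expect_equal(teager_energy(sin(0.5 * r)),
               log10((766 / 768) * sin(0.5)^2), tolerance = 1e-6)
  expect_error(teager_energy(c(1, 2)), "3 samples")
})

test_that("Higuchi FD: line ~1, white noise ~2, roughness ordering", {
  expect_equal(higuchi_fd(seq_len(768), k_max = 10), 1, tolerance = 0.05)
  fds <- vapply(1:20, function(s)
    higuchi_fd(eegselect:::with_seed(s, rnorm(768)), k_max = 10), 0)
  expect_gt(mean(fds), 1.85)
  expect_lt(mean(fds), 2.05)
  sine <- sin(2 * pi * 4 * (0:767) / 128)
  noise <- eegselect:::with_seed(99, rnorm(768))
  expect_gt(higuchi_fd(noise, 10), higuchi_fd(sine, 10))
  expect_true(all(fds >= 1 - 0.05 & fds <= 2 + 0.05))
  expect_error(higuchi_fd(1:10, k_max = 5), "k_max")
  expect_warning(fd0 <- higuchi_fd(rep(1, 768), 10), "constant")
  expect_equal(fd0, 0)
})

test_that("curve-length profile: L(k) is the mean of the L_m(k)", {
  x <- pink_noise(768, 1)
  for (k in c(2, 5, 10)) {
    prof <- curve_length_profile(x, k)
    expect_length(prof$L_m_values, k)
    expect_true(all(prof$L_m_values >= 0))
    expect_equal(prof$L, mean(prof$L_m_values))
  }
})

test_that("Petrosian FD: closed forms and monotonicity in sign changes", {
  expect_equal(petrosian_fd(1:100), 1)
  expect_equal(petrosian_fd(rep(c(1, -1), 50)),
               2 / (2 + log10(100 / (100 + 0.4 * 98))))
  # strictly increasing in the number of sign changes at fixed n
  make_sig <- function(n_changes, n = 101) {
    # piecewise monotone signal with exactly n_changes direction changes
    seg <- floor((n - 1) / (n_changes + 1))
    d <- rep(rep(c(1, -1), length.out = n_changes + 1), each = seg)
    d <- c(d, rep(d[length(d)], (n - 1) - length(d)))
    cumsum(c(0, d + 0.1))
  }
  fds <- vapply(c(0, 5, 20, 49), function(nc) petrosian_fd(make_sig(nc)), 0)
  expect_true(all(diff(fds) > 0))
})

test_that("energies shift by 2 log10|a| under scaling; FDs are invariant", {
  x <- pink_noise(768, 11)
  for (a in c(0.05, 3, 40)) {
    expect_equal(instantaneous_energy(a * x) - instantaneous_energy(x),
                 2 * log10(abs(a)), tolerance = 1e-9)
    expect_equal(teager_energy(a * x) - teager_energy(x),
                 2 * log10(abs(a)), tolerance = 1e-9)
    expect_equal(higuchi_fd(a * x, 10), higuchi_fd(x, 10),
                 tolerance = 1e-6)
    expect_equal(petrosian_fd(a * x), petrosian_fd(x), tolerance = 1e-6)
  }
})

test_that("per-channel vectors have the contracted lengths", {
  x <- pink_noise(768, 2)
  expect_length(channel_features(x, "DWT"), 20)
  expect_length(channel_features(x, "EMD"), 8)
  vz <- channel_features(rep(0, 768), "DWT")
  expect_length(vz, 20)
  expect_equal(unname(vz[seq(1, 20, by = 4)]), rep(-12, 5))  # energies
  expect_equal(unname(vz[seq(3, 20, by = 4)]), rep(0, 5))    # Higuchi
  expect_equal(unname(vz[seq(4, 20, by = 4)]), rep(1, 5))    # Petrosian
})

test_that("feature tables have C*F columns, block slicing, determinism", {
  # short epochs keep the 22-channel build cheap; lengths are contractual
  data <- array(eegselect:::with_seed(8, rnorm(22 * 64 * 4)),
                dim = c(22, 64, 4))
  es <- epoch_set(data, c(0L, 0L, 1L, 1L), fs = 128,
                  channel_labels = chb_montage)
  ft_dwt <- build_feature_table(es, "DWT")
  expect_equal(ncol(ft_dwt$matrix), 440)    # 22 x 20
  ft_emd <- build_feature_table(es, "EMD")
  expect_equal(ncol(ft_emd$matrix), 176)    # 22 x 8
  cols <- eegselect:::subset_columns(ft_dwt, 3)
  expect_identical(cols, ft_dwt$block_index[[3]])
  expect_length(cols, 20)
  expect_true(all(startsWith(colnames(ft_dwt$matrix)[cols], "T7-P7__")))
  # block ranges partition the columns in montage order
  expect_identical(unname(unlist(ft_dwt$block_index)),
                   seq_len(ncol(ft_dwt$matrix)))
  ft_again <- build_feature_table(es, "DWT")
  expect_identical(ft_dwt$matrix, ft_again$matrix)
})

test_that("feature table CSV round trip is lossless", {
  ft <- planted_table(seed = 3, n_per_class = 5)
  f <- withr::local_tempfile(fileext = ".csv")
  write_feature_table(ft, f)
  header <- readLines(f, n = 1)
  expect_match(header, "^label,CH1__A4__instE,")
  back <- read_feature_table(f)
  expect_identical(back$labels, ft$labels)
  expect_equal(back$matrix, ft$matrix, tolerance = 0)
  expect_identical(back$block_index, ft$block_index)
  expect_identical(back$method, ft$method)
})
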