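# EDF reader/writer, downsampling, and annotation-driven epoching.

make_rec <- function(n = 768, C = 3, fs = 128, seed = 5) {
  sig <- do.call(rbind, lapply(seq_len(C), function(i)
    pink_noise(n, seed + i) * i))
  recording(sig, fs, c("FP1-F7", "F7-T7", "T7-P7")[seq_len(C)])
}

test_that("EDF round trip is exact to the 16-bit quantization step", {
  rec <- make_rec()
  f <- withr::local_tempfile(fileext = ".edf")
  write_edf(rec, f)
  back <- load_recording(f)
  expect_identical(back$channel_labels, rec$channel_labels)
  expect_equal(back$fs, rec$fs)
  for (i in 1:3) {
    qstep <- (max(rec$signals[i, ]) - min(rec$signals[i, ])) / 65535
    expect_lte(max(abs(back$signals[i, ] - rec$signals[i, ])), qstep)
  }
})

test_that("write/read/write is byte-stable and headers hold fs", {
  rec <- make_rec()
  f1 <- withr::local_tempfile(fileext = ".edf")
  f2 <- withr::local_tempfile(fileext = ".edf")
  f3 <- withr::local_tempfile(fileext = ".edf")
  write_edf(rec, f1)
  write_edf(load_recording(f1), f2)
  write_edf(load_recording(f2), f3)
  expect_identical(readBin(f2, "raw", file.size(f2)),
                   readBin(f3, "raw", file.size(f3)))
  expect_equal(load_recording(f1)$fs, 128)
})

test_that("EDF error contracts: truncation, montage, bad input", {
  rec <- make_rec()
  f <- withr::local_tempfile(fileext = ".edf")
  write_edf(rec, f)
  trunc <- withr::local_tempfile(fileext = ".edf")
  writeBin(readBin(f, "raw", 1500), trunc)
  expect_error(load_recording(trunc), "format error")
  expect_error(load_recording(f, require_labels = c("FP1-F7", "CZ-PZ")),
               "montage error.*CZ-PZ")
  expect_error(write_edf(recording(matrix(0, 0, 10), 128, character(0)),
                         f), "empty|unique")
  bad <- rec
  bad$signals[1, 1] <- NA
  expect_error(write_edf(bad, f), "finite")
})

test_that("downsample keeps passband tones and kills aliases", {
  expect_identical(downsample(1:10, 128, 128), 1:10)
  t <- (0:1535) / 256
  y <- downsample(sin(2 * pi * 10 * t), 256, 128)
  expect_length(y, 768)
  pg <- eegselect:::periodogram_power(y, 128)
  expect_equal(pg$freq[which.max(pg$power)], 10)
  y100 <- downsample(sin(2 * pi * 100 * t), 256, 128)
  att_db <- 10 * log10(mean(sin(2 * pi * 100 * t)^2) / mean(y100^2))
  expect_gt(att_db, 20)
  expect_error(downsample(1:100, 256, 100), "integer multiple")
})

test_that("epoching is balanced, seeded, and boundary-respecting", {
  rec <- recording(matrix(rnorm(2 * 60 * 128), nrow = 2), 128, c("A", "B"))
  ivs <- seizure_intervals(10, 22)
  ep <- epoch_and_label(rec, ivs, epoch_s = 6, seed = 2)
  expect_equal(dim(ep$data)[3], 4)          # floor(12/6) windows per class
  expect_equal(sum(ep$labels == 1L), 2)
  expect_equal(sum(ep$labels == 0L), 2)
  ep2 <- epoch_and_label(rec, ivs, epoch_s = 6, seed = 2)
  expect_identical(ep$data, ep2$data)
  # seizure epochs match the interval content exactly (no straddling)
  expect_identical(ep$data[, , 3], rec$signals[, (10 * 128 + 1):(16 * 128)])
  expect_identical(ep$data[, , 4], rec$signals[, (16 * 128 + 1):(22 * 128)])
  expect_error(epoch_and_label(rec, seizure_intervals(10, 14), 6, 1),
               "empty-class")
  expect_error(epoch_and_label(rec, data.frame(start_s = numeric(0),
                                               end_s = numeric(0)), 6, 1),
               "empty-class")
})

test_that("epoch sets survive the EDF directory round trip", {
  cfg <- synth_config(n_channels = 3, informative_channels = 1,
                      n_per_class = 2, snr = 2, seed = 5)
  es <- generate_epochs(cfg)
  dir <- withr::local_tempdir()
  export_epochs(es, dir)
  expect_true(file.exists(file.path(dir, "class0.edf")))
  back <- import_epochs(dir)
  expect_identical(back$labels, es$labels)
  expect_equal(dim(back$data), dim(es$data))
  # quantization-bounded agreement
  expect_lt(max(abs(back$data - es$data)), 1e-3)
})
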