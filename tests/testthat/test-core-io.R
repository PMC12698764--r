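test_that("event lists validate, sort, and merge overlapping intervals", {
  ev <- event_list(c(35, 10), c(60, 40))
  expect_equal(nrow(ev), 1)
  expect_equal(c(ev$onset, ev$offset), c(10, 60))

  ev2 <- event_list(c(10, 50), c(20, 60))
  expect_equal(nrow(ev2), 2)
  expect_error(event_list(10, 10), class = "eegedge_validation_error")
  expect_error(event_list(40, 10), class = "eegedge_validation_error")

  # different labels never merge
  ev3 <- rbind(event_list(10, 40, "seizure"), event_list(35, 60, "alarm"))
  expect_equal(nrow(ev3), 2)
})

test_that("annotation summaries round-trip and merge overlapping seizures", {
  path <- withr::local_tempfile(fileext = ".txt")
  write_annotation_summary(event_list(c(10, 100), c(40, 130)), path,
                           file_name = "rec.edf", fs = 256)
  ev <- read_annotation_summary(path)
  expect_equal(nrow(ev), 2)
  expect_equal(ev$onset, c(10, 100))
  expect_equal(ev$offset, c(40, 130))

  writeLines(c("File Name: x.edf", "Number of Seizures in File: 0"), path)
  expect_equal(nrow(read_annotation_summary(path)), 0)

  writeLines(c("Seizure 1 Start Time: 10 seconds",
               "Seizure 1 End Time: 40 seconds",
               "Seizure 2 Start Time: 35 seconds",
               "Seizure 2 End Time: 60 seconds"), path)
  merged <- read_annotation_summary(path)
  expect_equal(nrow(merged), 1)
  expect_equal(c(merged$onset, merged$offset), c(10, 60))

  writeLines(c("Seizure 1 Start Time: 50 seconds",
               "Seizure 1 End Time: 20 seconds"), path)
  expect_error(read_annotation_summary(path), "line 1",
               class = "eegedge_validation_error")
})

test_that("EDF files round-trip within one quantization step", {
  rec <- tiny_background(fs = 64, duration_s = 10)
  path <- withr::local_tempfile(fileext = ".edf")
  write_edf(rec, path)
  back <- read_edf(path)
  expect_equal(back$fs, rec$fs)
  expect_equal(back$channel_labels, rec$channel_labels)
  expect_equal(back$montage, "bipolar")
  # quantization step: channel range over the 16-bit span
  step <- apply(abs(rec$samples), 2, max) * 2 / 65535
  for (i in seq_len(ncol(rec$samples))) {
    expect_lt(max(abs(back$samples[, i] - rec$samples[, i])), step[i] * 1.01)
  }
})

test_that("EDF reader flags bipolar 256 Hz layouts and rejects bad input", {
  tm <- seq(0, 4 - 1 / 256, by = 1 / 256)
  rec <- eeg_recording(cbind(sin(2 * pi * 5 * tm), cos(2 * pi * 5 * tm)) * 1e-5,
                       256, c("F7-T7", "F8-T8"), montage = "bipolar")
  path <- withr::local_tempfile(fileext = ".edf")
  write_edf(rec, path)
  back <- read_edf(path)
  expect_equal(back$fs, 256)
  expect_equal(back$montage, "bipolar")
  expect_equal(back$channel_labels, c("F7T7", "F8T8"))

  empty <- withr::local_tempfile(fileext = ".edf")
  file.create(empty)
  expect_error(read_edf(empty), class = "eegedge_format_error")

  # corrupt the number-of-signals field
  raw <- readBin(path, "raw", file.info(path)$size)
  raw[253:256] <- charToRaw("abcd")
  writeBin(raw, empty)
  expect_error(read_edf(empty), "signals", class = "eegedge_format_error")
})

test_that("EDF reader rejects mixed per-signal sampling rates", {
  rec <- tiny_background(fs = 64, duration_s = 4)
  path <- withr::local_tempfile(fileext = ".edf")
  write_edf(rec, path)
  raw <- readBin(path, "raw", file.info(path)$size)
  # per-signal samples-per-record field starts at byte 256 + 216*ns
  off <- 256 + 216 * 2
  raw[(off + 1):(off + 8)] <- charToRaw(sprintf("%-8d", 32))
  writeBin(raw, path)
  expect_error(read_edf(path), "mixed", class = "eegedge_format_error")
})

test_that("bipolar re-referencing equals channel subtraction and is linear", {
  n <- 512
  set.seed(5)
  s <- rnorm(n); r <- rnorm(n); extra <- rnorm(n)
  rec <- eeg_recording(cbind(F7 = s + r, T7 = r, F8 = extra + r, T8 = r),
                       fs = 64, montage = "referential")
  bp <- to_bipolar(rec, list(c("F7", "T7"), c("F8", "T8")))
  expect_equal(bp$channel_labels, c("F7T7", "F8T8"))
  expect_equal(bp$samples[, "F7T7"], s)            # reference cancels exactly
  expect_equal(bp$samples[, "F8T8"], extra)
  expect_equal(bp$montage, "bipolar")

  # identical electrodes cancel to zero
  rec2 <- eeg_recording(cbind(F7 = s, T7 = s), 64, montage = "referential")
  expect_true(all(to_bipolar(rec2, list(c("F7", "T7")))$samples == 0))

  # brute-force subtraction oracle + linearity
  set.seed(6)
  x <- matrix(rnorm(2 * n), ncol = 2)
  rec3 <- eeg_recording(x, 64, c("F7", "T7"), montage = "referential")
  expect_equal(to_bipolar(rec3, list(c("F7", "T7")))$samples[, 1],
               x[, 1] - x[, 2])
  rec3b <- rec3; rec3b$samples <- 3 * rec3$samples
  expect_equal(to_bipolar(rec3b, list(c("F7", "T7")))$samples,
               3 * to_bipolar(rec3, list(c("F7", "T7")))$samples)

  expect_error(to_bipolar(rec3, list(c("F7", "T8"))), "T8",
               class = "eegedge_validation_error")
  expect_error(to_bipolar(to_bipolar(rec3, list(c("F7", "T7")))),
               class = "eegedge_validation_error")
})

test_that("CSV recordings round-trip with inferred sampling rate", {
  rec <- tiny_background(fs = 64, duration_s = 5)
  path <- withr::local_tempfile(fileext = ".csv")
  write_csv_recording(rec, path)
  back <- read_csv_recording(path, montage = "bipolar")
  expect_equal(back$fs, 64, tolerance = 1e-9)
  expect_equal(back$samples, rec$samples, tolerance = 1e-9,
               ignore_attr = TRUE)
})

test_that("acquisition spec ties resolution to vref, gain, and bits", {
  spec <- acquisition_spec(fs = 250, pga_gain = 24, vref = 4.5, bits = 24)
  expect_equal(spec$resolution_uV, 2 * 4.5 / (24 * 2^24) * 1e6)
  expect_equal(spec$resolution_uV, 0.023, tolerance = 0.03)
  expect_error(acquisition_spec(pga_gain = 0),
               class = "eegedge_validation_error")
})

test_that("channel label normalization handles case, spacing, and pairs", {
  expect_equal(normalize_channel_label(c("f7 - t7", "F8-T8", " t7 ")),
               c("F7T7", "F8T8", "T7"))
})
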