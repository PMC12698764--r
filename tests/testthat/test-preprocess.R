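test_that("average removal cancels common-mode and offsets", {
  set.seed(2)
  c1 <- rnorm(256)
  rec <- eeg_recording(cbind(c1, -c1), 64, c("F7T7", "F8T8"),
                       montage = "bipolar")
  out <- remove_average(rec)
  expect_equal(out$samples, rec$samples)       # already zero-mean per sample

  x <- matrix(rnorm(256 * 4), ncol = 4)
  rec4 <- eeg_recording(x + 50e-6, 64, paste0("C", 1:4))
  out4 <- remove_average(rec4)
  expect_lt(max(abs(rowMeans(out4$samples))), 1e-15)

  single <- eeg_recording(cbind(c1), 64, "F7T7", montage = "bipolar")
  expect_error(remove_average(single), ">= 2",
               class = "eegedge_validation_error")

  # running-mean mode removes a slow drift
  drift <- eeg_recording(cbind(seq(0, 1e-4, length.out = 64 * 20)), 64, "F7")
  out_rm <- remove_average(drift, "running_mean", length_s = 1)
  mid <- 200:1000
  expect_lt(max(abs(out_rm$samples[mid, 1])), 1e-6)
})

test_that("zero-phase band-pass preserves pass-band amplitude with no lag", {
  rec <- sine_recording(10, fs = 256, duration_s = 10)
  out <- bandpass(rec, 1, 20, order = 4, zero_phase = TRUE)
  core <- (256 * 2):(256 * 8)                  # steady state, clear of edges
  amp <- max(abs(out$samples[core, 1]))
  expect_gte(amp, 0.98); expect_lte(amp, 1.005)
  cc <- stats::ccf(out$samples[core, 1], rec$samples[core, 1], lag.max = 20,
                   plot = FALSE)
  expect_equal(cc$lag[which.max(cc$acf)], 0)

  # DC is removed
  dc <- eeg_recording(cbind(rep(1, 2048)), 256, "F7T7", montage = "bipolar")
  expect_lt(sqrt(mean(bandpass(dc, 1, 20)$samples^2)), 1e-3)

  # stop-band: 50 Hz attenuated by > 40 dB in steady state
  hum <- sine_recording(50, fs = 256, duration_s = 10)
  out50 <- bandpass(hum, 1, 20, order = 4)
  atten_db <- 20 * log10(max(abs(out50$samples[(256 * 3):(256 * 7), 1])))
  expect_lt(atten_db, -40)

  expect_error(bandpass(rec, 1, 200), class = "eegedge_validation_error")
  expect_error(bandpass(rec, 0, 20), class = "eegedge_validation_error")

  # pass-band idempotence: a second pass changes amplitude < 2 %
  out2 <- bandpass(out, 1, 20, order = 4)
  expect_gt(max(abs(out2$samples[core, 1])) / amp, 0.98)
})

test_that("window plans tile recordings with the documented counts", {
  rec <- tiny_background(fs = 256, duration_s = 60, seed = 2)
  w <- make_windows(rec, window_plan(4, 0.5))
  expect_equal(length(w$starts), 113)          # floor((60-4)/0.5)+1
  expect_equal(w$starts[1], 0)
  expect_equal(w$starts[2] - w$starts[1], 0.5)
  expect_equal(nrow(w$segments$F7T7), 1024)
  # window contents match direct slicing
  expect_equal(w$segments$F7T7[, 5], rec$samples[513:1536, 1])

  one <- make_windows(tiny_background(fs = 64, duration_s = 4),
                      window_plan(4, 0.5))
  expect_equal(length(one$starts), 1)

  expect_warning(
    short <- make_windows(tiny_background(fs = 64, duration_s = 2),
                          window_plan(4, 0.5)), "shorter")
  expect_equal(length(short$starts), 0)

  # workload plan: 56 s windows at 60 % overlap step 22.4 s
  plan <- window_plan(56, 56 * 0.4)
  expect_equal(plan$step_s, 22.4)
  expect_equal(plan$overlap_fraction, 0.6)

  # step = win: 0 % overlap partitioning the usable span
  w2 <- make_windows(rec, window_plan(4, 4))
  expect_equal(length(w2$starts), 15)
  expect_equal(unname(diff(w2$starts)), rep(4, 14))
})

test_that("wavelet enhancement conserves energy and localizes bands", {
  set.seed(9)
  x <- rnorm(256)
  pyr <- dwt_enhance(x, "db4", 4)
  energy <- sum(vapply(unclass(pyr), function(m) sum(m^2), 0))
  expect_equal(energy, sum(x^2), tolerance = 1e-9)

  # perfect reconstruction (impulse and noise)
  imp <- c(1, rep(0, 255))
  expect_equal(as.numeric(dwt_reconstruct(dwt_enhance(imp))), imp,
               tolerance = 1e-10)
  expect_equal(as.numeric(dwt_reconstruct(pyr)), x, tolerance = 1e-9)

  # a 20 Hz tone at 256 Hz concentrates in d3 ([16, 32] Hz)
  tone <- sin(2 * pi * 20 * (0:1023) / 256)
  pt <- dwt_enhance(tone, "db4", 4)
  en <- vapply(unclass(pt), function(m) sum(m^2), 0)
  expect_equal(names(which.max(en)), "d3")
  # a 6 Hz tone falls below d4's [8, 16] Hz band -> approximation a4
  tone6 <- sin(2 * pi * 6 * (0:1023) / 256)
  en6 <- vapply(unclass(dwt_enhance(tone6)), function(m) sum(m^2), 0)
  expect_equal(names(which.max(en6)), "a4")
  expect_error(dwt_enhance(x, "sym5"), "db4",
               class = "eegedge_validation_error")
  expect_error(dwt_enhance(rnorm(8), "db4", 4),
               class = "eegedge_validation_error")
})

test_that("artifact rejection masks exactly the contaminated windows", {
  rec <- tiny_background(fs = 64, duration_s = 120, seed = 12)
  w <- make_windows(rec, window_plan(4, 0.5))
  clean <- reject_artifacts(w)
  expect_equal(sum(clean$mask), 0)
  expect_equal(length(clean$mask), length(w$starts))

  # inject a 500 uV blink near t = 60 s on channel 1
  rec2 <- rec
  blip <- round(60 * 64)
  t_blip <- (blip - 1) / 64
  rec2$samples[blip, 1] <- rec2$samples[blip, 1] + 500e-6
  w2 <- make_windows(rec2, window_plan(4, 0.5))
  masked <- reject_artifacts(w2)
  hit <- which(masked$mask)
  covering <- which(w2$starts <= t_blip & w2$starts + 4 > t_blip)
  expect_equal(hit, covering)

  none <- reject_artifacts(w2, max_abs_uV = Inf, max_rms_ratio = Inf)
  expect_false(any(none$mask))
})
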