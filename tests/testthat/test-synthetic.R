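test_that("background generator matches its spectral-slope contract", {
  spec <- synth_spec(fs = 64, duration_s = 60, seed = 7, noise_rms_uV = 0)
  rec <- gen_background(spec)
  psd <- welch_psd(rec, epoch_s = 4)
  sel <- psd$freq >= 2 & psd$freq <= 30
  slope <- stats::coef(stats::lm(log10(psd$psd[sel]) ~ log10(psd$freq[sel])))[2]
  expect_lt(abs(slope - (-1)), 0.3)

  # all amplitudes zero -> identically zero signal
  silent <- synth_spec(fs = 64, duration_s = 5, seed = 1, noise_rms_uV = 0,
                       background = list(slope = 1, rms_uV = 0,
                                         oscillations = list()))
  expect_true(all(gen_background(silent)$samples == 0))

  # identical seed: bit-identical; generators leave global RNG untouched
  set.seed(123); before <- rnorm(1)
  a <- gen_background(spec)
  set.seed(123)
  b <- gen_background(spec)
  expect_identical(a$samples, b$samples)
  set.seed(123); expect_identical(rnorm(1), before)

  expect_error(synth_spec(duration_s = -1),
               class = "eegedge_validation_error")
})

test_that("alpha sessions synchronize band power during eye closure", {
  spec <- synth_spec(fs = 64, duration_s = 60, seed = 4,
                     alpha = list(center_hz = 10, amp_uV = 20,
                                  closures = list(c(30, 60))))
  rec <- gen_alpha_session(spec)
  expect_equal(nrow(rec$events), 1)
  expect_equal(rec$events$offset - rec$events$onset, 30)
  band <- function(x) {
    p <- welch_psd(x, 64, epoch_s = 4)
    sum(p$psd[p$freq >= 8 & p$freq < 12]) * (p$freq[2] - p$freq[1])
  }
  closed <- band(rec$samples[(30 * 64 + 1):(60 * 64), 1])
  open <- band(rec$samples[1:(30 * 64), 1])
  expect_gt(closed / open, 5)

  # no closures: alpha never switches on
  spec0 <- synth_spec(fs = 64, duration_s = 20, seed = 4,
                      alpha = list(center_hz = 10, amp_uV = 20,
                                   closures = list()))
  rec0 <- gen_alpha_session(spec0)
  expect_equal(nrow(rec0$events), 0)
  expect_lt(band(rec0$samples[, 1]) /
              band(gen_background(spec0)$samples[, 1]), 1.5)

  expect_warning(gen_alpha_session(
    synth_spec(fs = 64, duration_s = 5, seed = 1,
               alpha = list(center_hz = 14, amp_uV = 5,
                            closures = list(c(0, 5))))), "outside")
})

test_that("seizure datasets annotate every discharge with strong contrast", {
  recs <- tiny_seizure_records(n_records = 10, duration_s = 400, seed = 31)
  expect_equal(sum(vapply(recs, function(r) nrow(r$events), 0L)), 10)

  r <- tiny_seizure_records(n_records = 1, duration_s = 600, seed = 5)[[1]]
  ev <- r$events
  tm <- (seq_len(nrow(r$samples)) - 1) / r$fs
  ict <- tm >= ev$onset[1] & tm < ev$offset[1]
  ratio <- sqrt(mean(r$samples[ict, 1]^2)) / sqrt(mean(r$samples[!ict, 1]^2))
  expect_gt(ratio, 4); expect_lt(ratio, 6)
  expect_gt(ratio, 3)    # the >= 3x background contract

  # seed change keeps annotations, varies waveforms
  spec <- synth_spec(fs = 64, duration_s = 300, seed = 1)
  tab <- list(data.frame(onset_s = 100, duration_s = 30, freq_hz = 4,
                         amp_uV = 100))
  a <- gen_seizure_dataset(spec, 1, tab)[[1]]
  spec$seed <- 2L
  b <- gen_seizure_dataset(spec, 1, tab)[[1]]
  expect_identical(a$events, b$events)
  expect_false(identical(a$samples, b$samples))

  expect_error(gen_seizure_dataset(
    spec, 1, list(data.frame(onset_s = 0, duration_s = 1000, freq_hz = 4,
                             amp_uV = 10))),
    class = "eegedge_validation_error")
})

test_that("dual-device views preserve, scale, and degrade as configured", {
  rec <- tiny_background(fs = 64, duration_s = 20, seed = 3)
  same <- gen_dual_device(rec, fs2 = rec$fs, jitter_s = 0, gain2 = 1,
                          noise2_uV = 0)
  expect_equal(same$samples, rec$samples, tolerance = 1e-12)

  # doubled gain shifts the Bland-Altman PSD difference positive
  twice <- gen_dual_device(rec, gain2 = 2)
  ba <- bland_altman(welch_psd(twice, epoch_s = 4),
                     welch_psd(rec, epoch_s = 4))
  expect_gt(ba$mean_difference, 0)

  expect_error(gen_dual_device(rec, fs2 = -1),
               class = "eegedge_validation_error")
})

test_that("noise-floor streams recover their configured RMS", {
  spec <- synth_spec(fs = 250, duration_s = 60, noise_rms_uV = 0.16, seed = 8)
  nf <- gen_noise_floor(spec)
  est <- irn_rms(nf$samples[, 1]) * 1e6
  expect_lt(abs(est - 0.16) / 0.16, 0.05)

  # zero noise: bounded by the quantization step / sqrt(12)
  spec0 <- synth_spec(fs = 250, duration_s = 60, noise_rms_uV = 0, seed = 8)
  nf0 <- gen_noise_floor(spec0)
  expect_lte(sqrt(mean(nf0$samples^2)),
             spec0$acquisition$resolution_v / sqrt(12))

  expect_warning(
    gen_noise_floor(synth_spec(fs = 250, duration_s = 39.996,
                               noise_rms_uV = 0.16, seed = 1)),
    "10,000")
})
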