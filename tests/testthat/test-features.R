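test_that("time-domain features match hand-computed oracles", {
  td <- time_domain(c(0, 1, 0, 1, 0))
  expect_equal(unname(td["line_length"]), 4)
  expect_equal(unname(td["mean_amplitude"]), 0.4)

  const <- time_domain(rep(3, 10))
  expect_equal(unname(const[c("line_length", "variance",
                              "hjorth_mobility", "hjorth_complexity")]),
               c(0, 0, 0, 0))
  expect_true(attr(const, "degenerate"))

  # discrete-difference closed form: mobility of a sinusoid = 2 sin(pi f/fs)
  fs <- 256; f <- 10
  x <- sin(2 * pi * f * (0:2047) / fs)
  expect_equal(unname(time_domain(x)["hjorth_mobility"]),
               2 * sin(pi * f / fs), tolerance = 1e-3)

  expect_error(time_domain(c(1, 2)), class = "eegedge_validation_error")
})

test_that("band powers localize tones and share out white noise by bandwidth", {
  fs <- 64
  x <- sin(2 * pi * 10 * (0:255) / fs)
  bp <- band_powers(x, fs)
  expect_gt(unname(bp["rbp_alpha"]), 0.95)
  expect_equal(sum(bp[5:8]), 1, tolerance = 1e-9)

  # flat-spectrum oracle: relative powers ~ bandwidth fractions, averaged
  # over windows to tame estimator variance
  set.seed(8)
  rel <- rowMeans(vapply(1:20, function(i) {
    band_powers(rnorm(256), fs)[5:8]
  }, numeric(4)))
  widths <- c(3, 4, 4, 8) / 19
  expect_true(all(abs(rel - widths) / widths < 0.2))

  z <- band_powers(rep(0, 256), fs)
  expect_true(all(z[1:4] == 0))
  expect_true(all(is.nan(z[5:8])))
  expect_true(attr(z, "zero_power"))
  expect_error(band_powers(rnorm(256), fs, bands = list(hf = c(20, 40))),
               "Nyquist", class = "eegedge_validation_error")
})

test_that("entropy features obey their closed-form limits", {
  expect_equal(eegedge:::entropy_from_probs(rep(0.1, 10)), log(10))

  expect_equal(permutation_entropy(1:50, 3), 0)
  expect_equal(permutation_entropy(seq(50, 1), 4), 0)

  set.seed(3)
  x <- rnorm(400)
  p <- eegedge:::hist_probs(x, 10)
  expect_equal(eegedge:::entropy_from_probs(p, "tsallis", 1 + 1e-9),
               eegedge:::entropy_from_probs(p), tolerance = 1e-6)
  expect_equal(eegedge:::entropy_from_probs(p, "renyi", 1),
               eegedge:::entropy_from_probs(p))

  # sample entropy agrees with an independent implementation
  expect_equal(sample_entropy(x, 2, 0.2 * sd(x)),
               pracma::sample_entropy(x, edim = 2, r = 0.2 * sd(x)),
               tolerance = 1e-12, ignore_attr = TRUE)

  # no-match sentinel
  se <- sample_entropy(c(seq_len(20)) * 100, m = 2, r = 1e-9)
  expect_true(is.infinite(se))
  expect_true(attr(se, "no_matches"))

  ent <- entropies(x)
  expect_named(ent, c("shannon", "tsallis", "renyi", "sample_entropy",
                      "permutation_entropy"))
})

test_that("the default registry has 56 uniquely named entries", {
  reg <- feature_registry()
  expect_equal(nrow(reg), 56)
  expect_equal(anyDuplicated(reg$name), 0)
  expect_equal(unname(table(reg$family)[c("time_domain", "band_power",
                                          "entropy", "dwt")]),
               c(8L, 8L, 10L, 30L), ignore_attr = TRUE)
})

test_that("matrix extraction agrees with the scalar feature path", {
  rec <- tiny_background(fs = 64, duration_s = 30, seed = 9)
  w <- make_windows(rec, window_plan(4, 2))
  fm <- extract_features(w)
  expect_equal(dim(fm), c(14, 112))
  expect_equal(length(attr(fm, "window_times")), 14)

  for (win in c(1, 7, 14)) {
    seg <- w$segments$F8T8[, win] * 1e6
    td <- time_domain(seg)
    expect_equal(unname(fm[win, paste0("F8T8.", names(td))]), unname(td),
                 tolerance = 1e-10, ignore_attr = TRUE)
    bp <- band_powers(seg, 64)
    expect_equal(unname(fm[win, paste0("F8T8.", names(bp))]), unname(bp),
                 tolerance = 1e-10, ignore_attr = TRUE)
    en <- entropies(seg)
    expect_equal(unname(fm[win, "F8T8.shannon_b10"]),
                 unname(en["shannon"]), tolerance = 1e-10)
    expect_equal(unname(fm[win, "F8T8.sampen_m2"]),
                 unname(en["sample_entropy"]), tolerance = 1e-10)
    expect_equal(unname(fm[win, "F8T8.permen_o3"]),
                 unname(en["permutation_entropy"]), tolerance = 1e-10)
    pyr <- dwt_enhance(seg)
    expect_equal(unname(fm[win, "F8T8.dwt_d1_rms"]),
                 sqrt(mean(pyr$d1^2)), tolerance = 1e-10)
  }

  # determinism and single-window extraction
  expect_identical(unclass(extract_features(w)), unclass(fm))
  one <- make_windows(tiny_background(fs = 64, duration_s = 4),
                      window_plan(4, 0.5))
  expect_equal(nrow(extract_features(one)), 1)

  # masking drops rows but keeps index bookkeeping
  mask <- rep(FALSE, 14); mask[c(2, 5)] <- TRUE
  fm_m <- extract_features(w, mask = mask)
  expect_equal(nrow(fm_m), 12)
  expect_equal(attr(fm_m, "kept_idx"), setdiff(1:14, c(2, 5)))
})

test_that("features scale as documented (covariant or invariant)", {
  set.seed(10)
  x <- rnorm(256)
  a <- 3.7
  td1 <- time_domain(x); td2 <- time_domain(a * x)
  expect_equal(unname(td2["line_length"]), a * unname(td1["line_length"]))
  expect_equal(unname(td2["variance"]), a^2 * unname(td1["variance"]))
  expect_equal(unname(td2["hjorth_mobility"]),
               unname(td1["hjorth_mobility"]))       # scale-invariant
  expect_equal(permutation_entropy(a * x, 3), permutation_entropy(x, 3))
  expect_equal(sample_entropy(a * x, 2, 0.2 * sd(a * x)),
               sample_entropy(x, 2, 0.2 * sd(x)), ignore_attr = TRUE)
})
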