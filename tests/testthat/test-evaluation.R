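test_that("time-slice folds are causal with the documented boundaries", {
  meta <- data.frame(duration_s = 36000)
  meta$events <- list(event_list(7200, 7260))
  plan <- tscv_split(meta, slice_h = 1)
  expect_equal(nrow(plan), 5)                  # 10 h, warm-up 5 h, 1 h slices
  expect_equal(plan$train_end_s[1], 18000)
  expect_equal(plan$test_end_s[5], 36000)
  # causality + exact tiling
  expect_true(all(plan$test_start_s >= plan$train_end_s))
  expect_equal(plan$test_start_s[-1], plan$test_end_s[-5])

  # seizure only at hour 9: warm-up is the first prefix containing it
  meta$events <- list(event_list(9 * 3600 + 10, 9 * 3600 + 70))
  plan2 <- tscv_split(meta, slice_h = 1)
  expect_equal(plan2$train_end_s[1], 9 * 3600 + 70)
  expect_equal(nrow(plan2), 1)

  # too little data -> skip with an insufficient-warm-up report
  short <- data.frame(duration_s = 4 * 3600)
  short$events <- list(event_list(100, 160))
  expect_error(tscv_split(short), "warm-up",
               class = "eegedge_validation_error")

  # per-record slices from a list of recordings
  recs <- tiny_seizure_records(fs = 64, duration_s = 600, n_records = 3)
  plan3 <- tscv_split(recs, min_train_h = 600 / 3600,
                      min_train_seizures = 1)
  expect_true(all(plan3$test_start_s >= plan3$train_end_s))
  expect_equal(plan3$test_end_s[nrow(plan3)], 1800)
})

test_that("event scoring implements any-overlap matching and FAR per day", {
  ref <- event_list(c(10, 100), c(40, 130))
  # self-scoring is perfect for any event list
  self <- score_events(ref, ref, total_time_h = 24)
  expect_equal(c(self$sens, self$prec, self$far_per_day), c(1, 1, 0))

  hyp <- event_list(c(35, 300), c(50, 310), "alarm")
  sc <- score_events(ref, hyp, total_time_h = 24)
  expect_equal(c(sc$tp, sc$fp, sc$fn), c(1L, 1L, 1L))
  expect_equal(sc$sens, 0.5)
  expect_equal(sc$prec, 0.5)
  expect_equal(sc$far_per_day, 1)

  # 2 false alarms in 24 h -> FAR 2/day
  sc2 <- score_events(event_list(), event_list(c(1, 50), c(2, 60), "alarm"),
                      total_time_h = 24)
  expect_equal(sc2$far_per_day, 2)
  expect_true(is.na(sc2$sens))                 # undefined, not 0

  expect_error(score_events(ref, hyp, total_time_h = 0),
               class = "eegedge_validation_error")

  # pre/post tolerance turns a near miss into a hit
  near <- event_list(41, 45, "alarm")
  expect_equal(score_events(ref, near, 24)$tp, 0L)
  expect_equal(score_events(ref, near, 24, tolerance_s = 2)$tp, 1L)
})

test_that("F1 and Gmean arithmetic reproduce published score tables", {
  expect_equal(round(f1_score(1.00, 0.75), 2), 0.86)
  # printed inputs carry 2-decimal rounding, so the band is one input ulp
  expect_lt(abs(f1_score(1.00, 0.38) - 0.56), 0.011)
  expect_equal(f1_score(0.5, 0.5), 0.5)
  expect_equal(f1_score(0.3, 0.7), f1_score(0.7, 0.3))   # symmetry
  expect_true(is.na(f1_score(NA, 0.5)))

  expect_equal(round(gmean_score(82.9, 66.1), 1), 74.0)
  expect_equal(round(gmean_score(73.3, 87.7), 1), 80.2)

  # every printed per-subject F1 follows from its Sens/Prec row
  for (config in c("glasses", "fullcap")) {
    tab <- reported_seizure_scores(config)
    f1 <- f1_score(tab$sens, tab$prec)
    f1[tab$sens + tab$prec == 0] <- 0
    expect_true(all(abs(f1 - tab$f1) <= 0.011))
  }
})

test_that("workload scoring returns percentages with the Sens*Spec Gmean", {
  sc <- score_cwm(tp = 40, tn = 40, fp = 10, fn = 10)
  expect_equal(sc$acc, 80)
  expect_equal(sc$sens, 80)
  expect_equal(sc$spec, 80)
  expect_equal(sc$gmean, 80)

  perfect <- score_cwm(50, 50, 0, 0)
  expect_equal(c(perfect$acc, perfect$spec, perfect$gmean), c(100, 100, 100))

  degenerate <- score_cwm(10, 0, 0, 0)
  expect_true(is.na(degenerate$spec))
  expect_error(score_cwm(-1, 0, 0, 0), class = "eegedge_validation_error")
})

test_that("macro-averaging matches the published Avg column and skips NAs", {
  agg <- aggregate_subjects(reported_seizure_scores("glasses"))
  expect_equal(round(agg$sens, 2), 0.64)
  expect_equal(round(agg$far_per_day, 2), 2.35)
  agg_fc <- aggregate_subjects(reported_seizure_scores("fullcap"))
  expect_equal(round(agg_fc$sens, 2), 0.80)

  one <- score_events(event_list(1, 5), event_list(2, 4, "alarm"), 10)
  expect_equal(aggregate_subjects(list(one))$sens, one$sens)

  df <- data.frame(sens = c(1, NA), prec = c(1, 0.5), f1 = c(1, NA),
                   far_per_day = c(0, 2))
  expect_equal(aggregate_subjects(df)$sens, 1)   # NA excluded, not zeroed
})

test_that("recursive elimination recovers planted informative features", {
  set.seed(3)
  n <- 120
  x <- cbind(matrix(rnorm(n * 10), n), matrix(rnorm(n * 50), n))
  colnames(x) <- paste0("f", 1:60)
  y <- rowSums(x[, 1:10]) > 0
  sel <- rfecv_select(x, y, folds = 5, n_trees = 50, seed = 2)
  expect_gte(sum(sel$selected %in% paste0("f", 1:10)), 8)

  # all-noise features: CV Gmean sits in the chance band
  set.seed(4)
  xn <- matrix(rnorm(n * 12), n); colnames(xn) <- paste0("n", 1:12)
  yn <- rep(c(TRUE, FALSE), n / 2)
  seln <- rfecv_select(xn, yn, folds = 5, n_trees = 50, step = 2, seed = 5)
  expect_lt(abs(seln$best_gmean - 50), 25)

  # fixed-size elimination reaches exactly the requested subset
  sel18 <- rfecv_select(x[, 1:30], y, folds = 5, n_keep = 18,
                        n_trees = 30, step = 3, seed = 6)
  expect_equal(length(sel18$selected), 18)

  expect_error(rfecv_select(x, y, folds = n + 1),
               class = "eegedge_validation_error")
})
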