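# End-to-end runners tying the modules into reproducible analyses.

#' Default seizure-detection configuration
#'
#' The operating point of the detection pipeline: zero-phase 4th-order
#' Butterworth band-pass over [1, 20] Hz, 4 s windows with a 0.5 s step
#' (87.5 % overlap), the 56-feature registry per channel, a seeded
#' probability forest, causal log-odds smoothing, and event building.
#'
#' @param band Band-pass edges (Hz).
#' @param filter_order Butterworth design order.
#' @param win_s,step_s Window plan (seconds).
#' @param n_trees Forest size.
#' @param horizon,prior Posterior-smoothing parameters.
#' @param threshold,min_duration_s,merge_gap_s Event-building parameters.
#' @param neg_pos_ratio Background windows kept per ictal window when
#'   training (class balance); `Inf` keeps everything.
#' @param min_train_h,min_train_seizures Warm-up requirements for the
#'   time-slice cross-validation.
#' @param seed Master seed.
#' @return Named list of class `detect_config`.
#' @export
detect_config <- function(band = c(1, 20), filter_order = 4, win_s = 4,
                          step_s = 0.5, n_trees = 100, horizon = 8,
                          prior = 0.5, threshold = 0.8, min_duration_s = 2,
                          merge_gap_s = 30, neg_pos_ratio = 10,
                          min_train_h = 5, min_train_seizures = 1,
                          seed = 1L) {
  structure(as.list(environment()), class = "detect_config")
}

# Preprocess + featurize one record with a config.
featurize_record <- function(rec, config, registry = feature_registry()) {
  rec <- bandpass(rec, config$band[1], config$band[2],
                  order = config$filter_order, zero_phase = TRUE)
  win <- make_windows(rec, window_plan(config$win_s, config$step_s))
  fm <- extract_features(win, registry)
  list(features = fm, windows = win,
       labels = label_windows(win, rec$events))
}

#' Run the full seizure-detection pipeline under TSCV
#'
#' Pre-processes and featurizes every record, builds the causal
#' time-slice cross-validation plan, and for each fold trains a forest on
#' all windows strictly before the fold boundary (background windows
#' down-sampled to `neg_pos_ratio` per ictal window), smooths the test
#' posteriors, builds alarm events, and scores them at the event level
#' against the annotations. Fold scores are pooled into one event score
#' over the whole test span.
#'
#' @param records List of [eeg_recording()]s forming one subject's
#'   timeline (consecutive).
#' @param config A [detect_config()].
#' @param progress Print per-fold progress lines.
#' @return List of class `detect_result`: `fold_scores` (data frame),
#'   `pooled` ([score_events()] over pooled counts), `plan`, `alarms`
#'   (per fold), `posteriors` (per fold), `config`.
#' @export
run_seizure_detection <- function(records, config = detect_config(),
                                  progress = FALSE) {
  assert_that(length(records) >= 1, "need at least one record")
  durs <- vapply(records, duration_s, 0)
  rec_starts <- cumsum(c(0, durs[-length(durs)]))
  for (i in seq_along(records)) records[[i]]$start_time <- rec_starts[i]

  feats <- lapply(records, featurize_record, config = config)
  plan <- tscv_split(records, min_train_h = config$min_train_h,
                     min_train_seizures = config$min_train_seizures)

  all_times <- unlist(lapply(feats, function(f) attr(f$features, "window_times")))
  all_labels <- unlist(lapply(feats, `[[`, "labels"))
  all_x <- do.call(rbind, lapply(feats, `[[`, "features"))

  fold_rows <- list()
  alarms <- list()
  posteriors <- list()
  for (k in seq_len(nrow(plan))) {
    tr_idx <- which(all_times + config$win_s <= plan$train_end_s[k])
    te_idx <- which(all_times >= plan$test_start_s[k] &
                      all_times < plan$test_end_s[k])
    if (!length(te_idx)) next
    y <- all_labels[tr_idx]
    pos <- which(y); neg <- which(!y)
    keep_neg <- if (is.finite(config$neg_pos_ratio) &&
                    length(neg) > config$neg_pos_ratio * length(pos)) {
      with_seed(config$seed + k,
                sort(sample(neg, config$neg_pos_ratio * length(pos))))
    } else {
      neg
    }
    use <- sort(c(pos, keep_neg))
    model <- train_rf(all_x[tr_idx[use], , drop = FALSE], y[use],
                      n_trees = config$n_trees, seed = config$seed + k)
    p <- predict_posteriors(model, all_x[te_idx, , drop = FALSE])
    wp <- window_posteriors(all_times[te_idx], p, win_s = config$win_s,
                            prior = config$prior, horizon = config$horizon,
                            threshold = config$threshold)
    al <- build_events(wp, min_duration_s = config$min_duration_s,
                       merge_gap_s = config$merge_gap_s)
    ref <- fold_reference_events(records, rec_starts,
                                 plan$test_start_s[k], plan$test_end_s[k])
    sc <- score_events(ref, al,
                       total_time_h = (plan$test_end_s[k] - plan$test_start_s[k]) / 3600)
    fold_rows[[length(fold_rows) + 1]] <- data.frame(
      fold = plan$fold[k], tp = sc$tp, fp = sc$fp, fn = sc$fn,
      sens = sc$sens, prec = sc$prec, f1 = sc$f1,
      far_per_day = sc$far_per_day, test_h = sc$total_time_h)
    alarms[[length(alarms) + 1]] <- al
    posteriors[[length(posteriors) + 1]] <- wp
    if (progress) {
      message(sprintf("fold %d: Tp=%d Fp=%d Fn=%d", plan$fold[k],
                      sc$tp, sc$fp, sc$fn))
    }
  }
  folds <- do.call(rbind, fold_rows)
  tot_h <- sum(folds$test_h)
  pooled <- list(tp = sum(folds$tp), fp = sum(folds$fp), fn = sum(folds$fn))
  pooled <- structure(list(
    tp = pooled$tp, fp = pooled$fp, fn = pooled$fn,
    sens = if (pooled$tp + pooled$fn > 0) pooled$tp / (pooled$tp + pooled$fn) else NA_real_,
    prec = if (pooled$tp + pooled$fp > 0) pooled$tp / (pooled$tp + pooled$fp) else NA_real_,
    f1 = NA_real_, far_per_day = pooled$fp * 24 / tot_h,
    total_time_h = tot_h), class = "event_score")
  pooled$f1 <- f1_score(pooled$sens, pooled$prec)
  structure(list(fold_scores = folds, pooled = pooled, plan = plan,
                 alarms = alarms, posteriors = posteriors, config = config),
            class = "detect_result")
}

# Reference seizure events inside a timeline span, in absolute seconds.
fold_reference_events <- function(records, rec_starts, from_s, to_s) {
  ons <- offs <- numeric(0)
  for (i in seq_along(records)) {
    ev <- records[[i]]$events
    if (!n_events(ev)) next
    ev <- ev[ev$label == "seizure", , drop = FALSE]
    if (!nrow(ev)) next
    on <- ev$onset + rec_starts[i]
    off <- ev$offset + rec_starts[i]
    keep <- off > from_s & on < to_s
    ons <- c(ons, on[keep]); offs <- c(offs, off[keep])
  }
  if (!length(ons)) return(event_list())
  event_list(ons, offs, "seizure")
}

#' @export
print.detect_result <- function(x, ...) {
  cat("<detect_result> ", nrow(x$fold_scores), " fold(s)\n", sep = "")
  print.data.frame(x$fold_scores, row.names = FALSE, digits = 3)
  cat("pooled: "); print(x$pooled)
  invisible(x)
}

#' The default synthetic seizure study conditions
#'
#' Ten one-hour two-channel records at 64 Hz with twelve annotated
#' seizures (one per record, two records carrying a second), rhythmic
#' 4 Hz discharges of 100 uV over a 20 uV pink background, occasional
#' blinks on the frontal channel. These are the fixed conditions the
#' package's end-to-end acceptance checks run under.
#'
#' @param seed Master seed (default 42).
#' @param n_records Number of one-hour records.
#' @return List of annotated [eeg_recording()]s.
#' @export
default_seizure_dataset <- function(seed = 42L, n_records = 10) {
  spec <- synth_spec(fs = 64, duration_s = 3600,
                     channels = c("F7T7", "F8T8"),
                     background = list(slope = 1, rms_uV = 20,
                                       oscillations = list(c(10, 5))),
                     artifacts = list(blink_rate_per_min = 0.5,
                                      blink_amp_uV = 120,
                                      blink_channels = "F7T7"),
                     noise_rms_uV = 0.5, seed = seed)
  onsets <- c(600, 1800, 2700, 900, 2200, 1300, 3000, 500, 1600, 2500)
  tables <- lapply(seq_len(n_records), function(r) {
    o <- onsets[(r - 1) %% length(onsets) + 1]
    sz <- data.frame(onset_s = o, duration_s = 60, freq_hz = 4, amp_uV = 100)
    if (r %in% c(3, 7)) {       # two records carry a second seizure
      sz <- rbind(sz, data.frame(onset_s = (o + 1200) %% 3400 + 100,
                                 duration_s = 45, freq_hz = 5, amp_uV = 90))
    }
    sz
  })
  gen_seizure_dataset(spec, n_records = n_records, seizure_table = tables)
}

#' Default workload-monitoring configuration
#'
#' 56 s windows with 60 % overlap (a 22.4 s step), a 200-tree forest, and
#' optional recursive feature elimination down to 18 features.
#'
#' @param win_s,overlap Window length (s) and fractional overlap.
#' @param n_trees Forest size (200; the full-cap variant uses 400).
#' @param n_features Features retained by RFECV (`NULL` disables
#'   selection).
#' @param rfecv_folds CV folds for the elimination harness.
#' @param seed Master seed.
#' @return Named list of class `cwm_config`.
#' @export
cwm_config <- function(win_s = 56, overlap = 0.6, n_trees = 200,
                       n_features = 18, rfecv_folds = 30, seed = 1L) {
  step_s <- win_s * (1 - overlap)
  structure(list(win_s = win_s, overlap = overlap, step_s = step_s,
                 n_trees = n_trees, n_features = n_features,
                 rfecv_folds = rfecv_folds, seed = seed),
            class = "cwm_config")
}

#' Generate a synthetic workload session
#'
#' Alternating low/high cognitive-load blocks: high-load blocks raise
#' frontal theta power and suppress alpha, the classic workload
#' signature. Block labels are annotated as events. Synthetic stand-in
#' for task-based workload recordings; not a physiological model.
#'
#' @param fs Sampling rate (Hz).
#' @param block_s Block length (seconds).
#' @param n_blocks Number of blocks (alternating low/high).
#' @param seed Integer seed.
#' @return An [eeg_recording()] with `"high_load"` events.
#' @export
gen_cwm_session <- function(fs = 64, block_s = 112, n_blocks = 12,
                            seed = 7L) {
  dur <- block_s * n_blocks
  spec <- synth_spec(fs = fs, duration_s = dur,
                     channels = c("F7", "T7", "F8", "T8"),
                     background = list(slope = 1, rms_uV = 15,
                                       oscillations = list()),
                     noise_rms_uV = 0.5, seed = seed)
  rec <- gen_background(spec)
  tm <- (seq_len(nrow(rec$samples)) - 1) / fs
  high <- ((tm %/% block_s) %% 2) == 1
  x <- rec$samples * 1e6
  with_seed(seed + 1, {
    for (i in seq_len(ncol(x))) {
      theta <- 12 * sin(2 * pi * 6 * tm + stats::runif(1, 0, 2 * pi))
      alpha <- 12 * sin(2 * pi * 10 * tm + stats::runif(1, 0, 2 * pi))
      x[, i] <- x[, i] + ifelse(high, theta, alpha)
    }
  })
  ev <- event_list(onset = block_s * seq(1, n_blocks - 1, by = 2),
                   offset = block_s * seq(2, n_blocks, by = 2),
                   label = "high_load")
  eeg_recording(x * 1e-6, fs, spec$channels, montage = "referential",
                events = ev)
}

#' Run the workload-monitoring pipeline
#'
#' Band-pass, 56 s windows with 60 % overlap, the 56-feature registry,
#' chronological train/test split, optional RFECV feature selection on
#' the training set, a 200-tree forest, and window-level scoring
#' (accuracy, sensitivity, specificity, Gmean).
#'
#' @param rec An [eeg_recording()] with `"high_load"` events labelling
#'   the positive class.
#' @param config A [cwm_config()].
#' @param train_fraction Chronological fraction used for training.
#' @return List of class `cwm_result`: `score` ([score_cwm()]),
#'   `selected` (feature names used), `n_train`, `n_test`.
#' @export
run_cwm <- function(rec, config = cwm_config(), train_fraction = 0.6) {
  rec <- bandpass(rec, 1, 20, order = 4)
  win <- make_windows(rec, window_plan(config$win_s, config$step_s))
  fm <- extract_features(win)
  y <- label_windows(win, rec$events)
  n <- nrow(fm)
  tr <- seq_len(floor(train_fraction * n))
  te <- setdiff(seq_len(n), tr)
  cols <- colnames(fm)
  if (!is.null(config$n_features) && config$n_features < length(cols)) {
    sel <- rfecv_select(fm[tr, , drop = FALSE], y[tr],
                        folds = min(config$rfecv_folds, length(tr)),
                        n_keep = config$n_features, n_trees = 50,
                        step = 0.2, seed = config$seed)
    cols <- sel$selected
  }
  model <- train_rf(fm[tr, cols, drop = FALSE], y[tr],
                    n_trees = config$n_trees, seed = config$seed)
  pred <- predict_posteriors(model, fm[te, cols, drop = FALSE]) >= 0.5
  truth <- y[te]
  sc <- score_cwm(tp = sum(pred & truth), tn = sum(!pred & !truth),
                  fp = sum(pred & !truth), fn = sum(!pred & truth))
  structure(list(score = sc, selected = cols, n_train = length(tr),
                 n_test = length(te)),
            class = "cwm_result")
}
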