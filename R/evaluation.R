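# Time-slice cross-validation, event-level seizure scoring, workload
# scoring, and the recursive feature-elimination harness.

#' Time-slice cross-validation plan
#'
#' Orders a subject's records on one timeline and emits causal folds: fold
#' k trains on everything before boundary k and tests on the next slice.
#' The first boundary (warm-up) is the earliest point with at least
#' `min_train_h` hours of data and `min_train_seizures` seizures before
#' it; the test slices tile everything after it exactly once.
#'
#' @param records List of [eeg_recording()]s (consecutive segments of one
#'   subject), or a data frame with columns `duration_s` and a list column
#'   `events`.
#' @param min_train_h Minimum warm-up hours (default 5).
#' @param min_train_seizures Minimum seizures in the warm-up (default 1).
#' @param slice_h Fixed test-slice length in hours; `NULL` (default) uses
#'   one slice per record.
#' @return Data frame of class `tscv_plan` with columns `fold`,
#'   `train_start_s`, `train_end_s`, `test_start_s`, `test_end_s`. An
#'   unsatisfiable warm-up raises a validation error tagged
#'   `"insufficient warm-up"`.
#' @export
tscv_split <- function(records, min_train_h = 5, min_train_seizures = 1,
                       slice_h = NULL) {
  if (is.data.frame(records)) {
    durs <- records$duration_s
    evs <- records$events
  } else {
    durs <- vapply(records, duration_s, 0)
    evs <- lapply(records, function(r) r$events)
  }
  starts <- cumsum(c(0, durs[-length(durs)]))
  total_s <- sum(durs)
  boundaries <- if (is.null(slice_h)) {
    cumsum(durs)
  } else {
    b <- seq(slice_h * 3600, total_s, by = slice_h * 3600)
    if (!length(b) || b[length(b)] < total_s) b <- c(b, total_s)
    b
  }
  # warm-up: the earliest instant with enough hours and enough completed
  # seizures before it (the first prefix containing the k-th seizure)
  seiz_offsets <- sort(unlist(lapply(seq_along(evs), function(i) {
    ev <- evs[[i]]
    if (!n_events(ev)) return(numeric(0))
    ev$offset[ev$label == "seizure"] + starts[i]
  })))
  if (length(seiz_offsets) < min_train_seizures) {
    stop_validation("insufficient warm-up: only ", length(seiz_offsets),
                    " seizure(s) available, ", min_train_seizures, " required")
  }
  warmup <- max(min_train_h * 3600,
                if (min_train_seizures > 0) seiz_offsets[min_train_seizures] else 0)
  if (warmup >= total_s) {
    stop_validation("insufficient warm-up: boundary at ", warmup / 3600,
                    " h leaves no data to test (", total_s / 3600, " h total)")
  }
  test_bounds <- boundaries[boundaries > warmup]
  plan <- data.frame(
    fold = seq_along(test_bounds),
    train_start_s = 0,
    train_end_s = c(warmup, test_bounds[-length(test_bounds)]),
    test_start_s = c(warmup, test_bounds[-length(test_bounds)]),
    test_end_s = test_bounds)
  class(plan) <- c("tscv_plan", "data.frame")
  plan
}

#' Event-level detection score
#'
#' Any-overlap matching: a reference event overlapped by at least one
#' alarm counts one true positive, otherwise one false negative; every
#' alarm overlapping no reference event counts one false positive. Then
#' `Sens = Tp/(Tp+Fn)`, `Prec = Tp/(Tp+Fp)`,
#' `F1 = 2*Prec*Sens/(Prec+Sens)`, and the false-alarm rate is normalized
#' to alarms per 24 h, `FAR = Fp*24/total_time_h`. Metrics with empty
#' denominators (e.g. sensitivity with no reference events) are `NA`
#' (not-applicable), never coerced to 0.
#'
#' @param ref Reference [event_list()].
#' @param hyp Hypothesis events: an `alarm_events` object or an
#'   [event_list()].
#' @param total_time_h Hours of data scored (> 0); required for FAR.
#' @param tolerance_s Pre/post tolerance added around reference events
#'   before overlap matching (default 0).
#' @return List of class `event_score`: `tp`, `fp`, `fn`, `sens`, `prec`,
#'   `f1`, `far_per_day`, `total_time_h`.
#' @export
score_events <- function(ref, hyp, total_time_h, tolerance_s = 0) {
  if (inherits(hyp, "alarm_events")) hyp <- hyp$events
  assert_that(is.numeric(total_time_h) && total_time_h > 0,
              "total_time_h must be positive")
  nr <- n_events(ref); nh <- n_events(hyp)
  overlap <- function(a_on, a_off, b_on, b_off) {
    pmin(a_off, b_off) - pmax(a_on, b_on) > 0
  }
  tp <- 0L; fn <- 0L
  hyp_hit <- rep(FALSE, nh)
  if (nr) {
    for (k in seq_len(nr)) {
      if (nh) {
        hits <- overlap(ref$onset[k] - tolerance_s, ref$offset[k] + tolerance_s,
                        hyp$onset, hyp$offset)
      } else {
        hits <- logical(0)
      }
      if (any(hits)) {
        tp <- tp + 1L
        hyp_hit <- hyp_hit | hits
      } else {
        fn <- fn + 1L
      }
    }
  }
  fp <- sum(!hyp_hit)
  sens <- if (nr) tp / (tp + fn) else NA_real_
  prec <- if (tp + fp > 0) tp / (tp + fp) else NA_real_
  f1 <- f1_score(sens, prec)
  structure(list(tp = tp, fp = fp, fn = fn, sens = sens, prec = prec,
                 f1 = f1, far_per_day = fp * 24 / total_time_h,
                 total_time_h = total_time_h),
            class = "event_score")
}

#' @export
print.event_score <- function(x, ...) {
  cat(sprintf("<event_score> Tp=%d Fp=%d Fn=%d | Sens=%.3f Prec=%.3f F1=%.3f FAR=%.2f/day (%.2f h)\n",
              x$tp, x$fp, x$fn, x$sens, x$prec, x$f1, x$far_per_day,
              x$total_time_h))
  invisible(x)
}

#' F1 score from sensitivity and precision
#'
#' `2*Prec*Sens/(Prec+Sens)`; `NA` when either input is `NA`, 0 when both
#' are 0.
#'
#' @param sens,prec Sensitivity and precision in `[0, 1]`.
#' @return F1 in `[0, 1]`.
#' @export
f1_score <- function(sens, prec) {
  ifelse(is.na(sens) | is.na(prec), NA_real_,
         ifelse(sens + prec == 0, 0, 2 * prec * sens / (prec + sens)))
}

#' Geometric mean of sensitivity and specificity
#'
#' The balance-robust summary used for workload classification. Although
#' some write-ups print the formula with precision in place of
#' specificity, published score tables are only consistent with
#' `sqrt(Sens * Spec)`, which is what this function computes.
#'
#' @param sens,spec Sensitivity and specificity (fractions or percent, as
#'   long as both share the unit).
#' @return `sqrt(sens * spec)` in the input unit.
#' @export
gmean_score <- function(sens, spec) sqrt(sens * spec)

#' Window-level workload classification score
#'
#' From window confusion counts: accuracy `(Tp+Tn)/total`, specificity
#' `Tn/(Tn+Fp)`, sensitivity `Tp/(Tp+Fn)`, and the geometric mean of
#' sensitivity and specificity. Returned as percentages. Zero denominators
#' yield `NA`.
#'
#' @param tp,tn,fp,fn Non-negative window counts.
#' @return List of class `cwm_score`: `acc`, `spec`, `sens`, `gmean` (all
#'   in percent) plus the counts.
#' @export
score_cwm <- function(tp, tn, fp, fn) {
  assert_that(all(c(tp, tn, fp, fn) >= 0), "counts must be non-negative")
  total <- tp + tn + fp + fn
  acc <- if (total > 0) 100 * (tp + tn) / total else NA_real_
  spec <- if (tn + fp > 0) 100 * tn / (tn + fp) else NA_real_
  sens <- if (tp + fn > 0) 100 * tp / (tp + fn) else NA_real_
  structure(list(acc = acc, spec = spec, sens = sens,
                 gmean = gmean_score(sens, spec),
                 tp = tp, tn = tn, fp = fp, fn = fn),
            class = "cwm_score")
}

#' @export
print.cwm_score <- function(x, ...) {
  cat(sprintf("<cwm_score> Acc=%.1f%% Sens=%.1f%% Spec=%.1f%% Gmean=%.1f%%\n",
              x$acc, x$sens, x$spec, x$gmean))
  invisible(x)
}

#' Macro-average event scores across subjects
#'
#' Unweighted arithmetic mean of each metric; `NA` (not-applicable)
#' entries are excluded from their metric's average rather than deflating
#' it.
#'
#' @param per_subject List of [score_events()] results (or a data frame
#'   with columns `sens`, `prec`, `f1`, `far_per_day`).
#' @return List with averaged `sens`, `prec`, `f1`, `far_per_day`, and
#'   `n_subjects`.
#' @export
aggregate_subjects <- function(per_subject) {
  if (!is.data.frame(per_subject)) {
    assert_that(length(per_subject) >= 1, "need at least one subject")
    per_subject <- data.frame(
      sens = vapply(per_subject, `[[`, 0, "sens"),
      prec = vapply(per_subject, `[[`, 0, "prec"),
      f1 = vapply(per_subject, `[[`, 0, "f1"),
      far_per_day = vapply(per_subject, `[[`, 0, "far_per_day"))
  }
  list(sens = mean(per_subject$sens, na.rm = TRUE),
       prec = mean(per_subject$prec, na.rm = TRUE),
       f1 = mean(per_subject$f1, na.rm = TRUE),
       far_per_day = mean(per_subject$far_per_day, na.rm = TRUE),
       n_subjects = nrow(per_subject))
}

# Window-level Gmean of predictions vs labels, in percent.
window_gmean <- function(pred, truth) {
  tp <- sum(pred & truth); tn <- sum(!pred & !truth)
  fp <- sum(pred & !truth); fn <- sum(!pred & truth)
  score_cwm(tp, tn, fp, fn)$gmean
}

#' Recursive feature elimination with cross-validation
#'
#' Ranks features by forest impurity importance, drops the weakest one per
#' iteration, and tracks the cross-validated geometric mean
#' (sensitivity/specificity) of each subset size. Returns the subset
#' maximizing CV Gmean (smallest subset on ties), or exactly `n_keep`
#' features when requested. Deterministic given the seed.
#'
#' @param features Numeric matrix (samples x features) with column names.
#' @param labels Logical or two-level factor labels.
#' @param folds Number of stratified CV folds (default 30); must not
#'   exceed the sample count.
#' @param n_keep Optional fixed subset size to eliminate down to.
#' @param n_trees Trees per forest fit.
#' @param step Features dropped per iteration: a count, or a fraction of
#'   the current subset when `< 1` (default 1, the weakest feature only).
#' @param seed Integer seed.
#' @return List of class `rfecv_result`: `selected` (feature names),
#'   `history` (data frame of subset size and CV Gmean), `best_gmean`.
#' @export
rfecv_select <- function(features, labels, folds = 30, n_keep = NULL,
                         n_trees = 100, step = 1, seed = 1L) {
  n <- nrow(features)
  if (folds > n) stop_validation("folds (", folds, ") exceed samples (", n, ")")
  if (is.logical(labels)) labels <- factor(labels, levels = c(FALSE, TRUE))
  labels <- droplevels(as.factor(labels))
  assert_that(nlevels(labels) == 2, "labels must have exactly two classes")
  fold_id <- with_seed(seed, {
    id <- integer(n)
    for (lv in levels(labels)) {
      ii <- which(labels == lv)
      id[ii] <- sample(rep_len(seq_len(folds), length(ii)))
    }
    id
  })
  pos <- levels(labels)[2]
  cv_gmean <- function(cols) {
    pred <- rep(NA, n)
    for (f in seq_len(folds)) {
      tr <- fold_id != f
      if (length(unique(labels[tr])) < 2) next
      fit <- train_rf(features[tr, cols, drop = FALSE], labels[tr],
                      n_trees = n_trees, seed = seed + f)
      pred[!tr] <- predict_posteriors(fit,
                                      features[!tr, cols, drop = FALSE]) >= 0.5
    }
    ok <- !is.na(pred)
    window_gmean(pred[ok] == 1, labels[ok] == pos)
  }
  cols <- colnames(features)
  history <- data.frame(size = integer(0), gmean = numeric(0))
  subsets <- list()
  repeat {
    g <- cv_gmean(cols)
    history <- rbind(history, data.frame(size = length(cols), gmean = g))
    subsets[[length(subsets) + 1]] <- cols
    if (length(cols) <= max(1, n_keep %||% 1)) break
    fit_all <- train_rf(features[, cols, drop = FALSE], labels,
                        n_trees = n_trees, seed = seed,
                        importance = "impurity")
    imp <- fit_all$model$variable.importance
    n_drop <- if (step < 1) max(1L, floor(step * length(cols))) else step
    n_drop <- min(n_drop, length(cols) - max(1, n_keep %||% 1))
    drop_feat <- cols[order(imp[make.names(cols)])[seq_len(n_drop)]]
    cols <- setdiff(cols, drop_feat)
  }
  if (!is.null(n_keep)) {
    pick <- which(history$size == max(n_keep, min(history$size)))[1]
  } else {
    best <- max(history$gmean, na.rm = TRUE)
    cand <- which(history$gmean >= best - 1e-9)
    pick <- cand[which.min(history$size[cand])]
  }
  structure(list(selected = subsets[[pick]], history = history,
                 best_gmean = history$gmean[pick]),
            class = "rfecv_result")
}
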