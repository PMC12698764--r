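# Random-forest window classification, causal Bayesian-style posterior
# smoothing, and conversion of window decisions into alarm events.

#' Label windows against an event list
#'
#' A window is labelled positive when at least `min_overlap` of its span
#' lies inside an annotated event.
#'
#' @param windows An [make_windows()] result (or a feature matrix carrying
#'   `window_times`/`win_s` attributes).
#' @param events An [event_list()].
#' @param min_overlap Minimum overlapped fraction of the window (default
#'   0.5).
#' @return Logical vector, one element per window.
#' @export
label_windows <- function(windows, events, min_overlap = 0.5) {
  starts <- if (inherits(windows, "eeg_windows")) windows$starts else attr(windows, "window_times")
  win_s <- if (inherits(windows, "eeg_windows")) windows$win_s else attr(windows, "win_s")
  lab <- rep(FALSE, length(starts))
  if (!n_events(events)) return(lab)
  for (k in seq_len(nrow(events))) {
    ov <- pmin(starts + win_s, events$offset[k]) - pmax(starts, events$onset[k])
    lab <- lab | (ov >= min_overlap * win_s)
  }
  lab
}

#' Train a random-forest window classifier
#'
#' A probability forest over the feature matrix; deterministic given the
#' seed (single-threaded). The model handle records the feature manifest,
#' and prediction refuses a matrix whose columns disagree with it.
#'
#' @param features Numeric matrix (windows x features), e.g. an
#'   [extract_features()] result.
#' @param labels Logical or factor per-window class labels; both classes
#'   must be present.
#' @param n_trees Number of trees (the workload-monitoring configuration
#'   uses 200; the full-cap variant 400).
#' @param seed Integer seed.
#' @param class_weights Optional named weights for `FALSE`/`TRUE` classes.
#' @return A `seizure_rf` model handle.
#' @export
train_rf <- function(features, labels, n_trees = 100, seed = 1L,
                     class_weights = NULL, importance = "none") {
  if (is.logical(labels)) labels <- factor(labels, levels = c(FALSE, TRUE))
  labels <- droplevels(as.factor(labels))
  if (nlevels(labels) < 2) {
    missing_class <- setdiff(c("FALSE", "TRUE"), levels(labels))
    stop_validation("training set has a single class; missing: ",
                    paste(missing_class, collapse = ", "))
  }
  df <- as.data.frame(unclass(features))
  names(df) <- make.names(colnames(features))
  df$.class <- labels
  fit <- ranger::ranger(
    dependent.variable.name = ".class", data = df,
    num.trees = n_trees, probability = TRUE, seed = as.integer(seed),
    num.threads = 1, class.weights = class_weights,
    importance = importance, respect.unordered.factors = TRUE)
  structure(list(model = fit, feature_names = colnames(features),
                 n_trees = n_trees, seed = as.integer(seed),
                 positive = levels(labels)[2]),
            class = "seizure_rf")
}

#' Per-window ictal posterior probabilities
#'
#' @param model A [train_rf()] handle.
#' @param features Feature matrix with the same columns the model was
#'   trained on.
#' @return Numeric vector of positive-class probabilities in `[0, 1]`.
#' @export
predict_posteriors <- function(model, features) {
  assert_that(inherits(model, "seizure_rf"), "model must be a seizure_rf")
  if (!identical(colnames(features), model$feature_names)) {
    stop_validation("feature columns do not match the model's manifest")
  }
  df <- as.data.frame(unclass(features))
  names(df) <- make.names(colnames(features))
  pr <- stats::predict(model$model, data = df, num.threads = 1)$predictions
  as.numeric(pr[, model$positive])
}

#' Causal Bayesian-style posterior smoothing
#'
#' Sequential log-odds accumulation over a sliding causal horizon: the
#' smoothed odds at window t are the prior odds times the product of the
#' window likelihood ratios `p/(1-p)` of the last `horizon` windows
#' (fewer at the start of the record). Probabilities are clipped to
#' `[1e-6, 1-1e-6]` before forming odds. With `horizon = 1` and an
#' uninformative prior the operation is the identity.
#'
#' @param p Numeric vector of window probabilities in `[0, 1]`.
#' @param prior Prior ictal probability (default 0.5, uninformative).
#' @param horizon Number of windows in the causal evidence window (>= 1).
#' @return Numeric vector of smoothed probabilities.
#' @export
smooth_posteriors <- function(p, prior = 0.5, horizon = 8) {
  if (any(p < 0 | p > 1, na.rm = TRUE)) {
    stop_validation("probabilities must lie in [0, 1]")
  }
  assert_that(horizon >= 1, "horizon must be >= 1")
  eps <- 1e-6
  pc <- pmin(pmax(p, eps), 1 - eps)
  l <- log(pc / (1 - pc))
  cs <- cumsum(l)
  run <- cs - c(rep(0, min(horizon, length(l))),
                cs[seq_len(max(0, length(l) - horizon))])
  logodds <- log(prior / (1 - prior)) + run
  sm <- stats::plogis(logodds)
  pmin(pmax(sm, eps), 1 - eps)
}

#' Window posteriors container
#'
#' @param window_times Window start times (seconds).
#' @param p_ictal Raw per-window probabilities.
#' @param win_s Window length (seconds).
#' @param prior,horizon Smoothing parameters passed to
#'   [smooth_posteriors()].
#' @param threshold Decision level attached for downstream event building.
#' @return An object of class `window_posteriors`.
#' @export
window_posteriors <- function(window_times, p_ictal, win_s = 4,
                              prior = 0.5, horizon = 8, threshold = 0.8) {
  structure(list(window_times = window_times, p_ictal = p_ictal,
                 smoothed = smooth_posteriors(p_ictal, prior, horizon),
                 win_s = win_s, threshold = threshold),
            class = "window_posteriors")
}

#' Turn window posteriors into alarm events
#'
#' Maximal runs of supra-threshold smoothed windows become candidate
#' events (onset at the first supra-threshold window start, offset at the
#' last window start plus the window length). Candidates shorter than
#' `min_duration_s` are dropped, then candidates separated by less than
#' `merge_gap_s` are merged. The peak smoothed posterior of each event is
#' reported.
#'
#' @param posteriors A [window_posteriors()] object.
#' @param threshold Decision level (default: the container's).
#' @param min_duration_s Minimum event duration (seconds).
#' @param merge_gap_s Events closer than this gap are merged (seconds).
#' @return List of class `alarm_events`: `events` (an [event_list()] with
#'   label `"alarm"`) and `peak_posterior` per event.
#' @export
build_events <- function(posteriors, threshold = NULL, min_duration_s = 2,
                         merge_gap_s = 30) {
  assert_that(inherits(posteriors, "window_posteriors"),
              "posteriors must be a window_posteriors object")
  thr <- threshold %||% posteriors$threshold
  sup <- posteriors$smoothed >= thr
  tms <- posteriors$window_times
  if (!any(sup)) {
    return(structure(list(events = event_list(), peak_posterior = numeric(0)),
                     class = "alarm_events"))
  }
  r <- rle(sup)
  ends <- cumsum(r$lengths)
  starts_i <- ends - r$lengths + 1
  on_i <- starts_i[r$values]
  off_i <- ends[r$values]
  onset <- tms[on_i]
  offset <- tms[off_i] + posteriors$win_s
  peak <- vapply(seq_along(on_i), function(k) {
    max(posteriors$smoothed[on_i[k]:off_i[k]])
  }, 0)
  keep <- (offset - onset) >= min_duration_s
  onset <- onset[keep]; offset <- offset[keep]; peak <- peak[keep]
  if (!length(onset)) {
    return(structure(list(events = event_list(), peak_posterior = numeric(0)),
                     class = "alarm_events"))
  }
  # merge events whose gap is below merge_gap_s, keeping the larger peak
  m_on <- onset[1]; m_off <- offset[1]; m_pk <- peak[1]
  out_on <- out_off <- out_pk <- numeric(0)
  for (k in seq_along(onset)[-1]) {
    if (onset[k] - m_off < merge_gap_s) {
      m_off <- max(m_off, offset[k]); m_pk <- max(m_pk, peak[k])
    } else {
      out_on <- c(out_on, m_on); out_off <- c(out_off, m_off)
      out_pk <- c(out_pk, m_pk)
      m_on <- onset[k]; m_off <- offset[k]; m_pk <- peak[k]
    }
  }
  out_on <- c(out_on, m_on); out_off <- c(out_off, m_off)
  out_pk <- c(out_pk, m_pk)
  structure(list(events = event_list(out_on, out_off, label = "alarm"),
                 peak_posterior = out_pk),
            class = "alarm_events")
}

#' @export
print.alarm_events <- function(x, ...) {
  cat("<alarm_events> ", n_events(x$events), " alarm(s)\n", sep = "")
  if (n_events(x$events)) {
    print.data.frame(cbind(x$events, peak = round(x$peak_posterior, 4)),
                     row.names = FALSE)
  }
  invisible(x)
}
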