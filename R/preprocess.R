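#' Sliding-window plan
#'
#' @param win_s Window length (seconds).
#' @param step_s Step between window starts (seconds), `0 < step_s <= win_s`.
#' @return An object of class `window_plan` with the implied
#'   `overlap_fraction = 1 - step_s/win_s` (so 4 s windows with a 0.5 s step
#'   overlap by 87.5 %).
#' @export
window_plan <- function(win_s = 4, step_s = 0.5) {
  assert_that(step_s > 0 && step_s <= win_s,
              "window plan requires 0 < step_s <= win_s")
  structure(list(win_s = win_s, step_s = step_s,
                 overlap_fraction = 1 - step_s / win_s),
            class = "window_plan")
}

#' Remove the signal average
#'
#' Two baseline-wander strategies: `"across_channels"` subtracts the
#' per-sample mean over channels (the common-mode estimate; needs >= 2
#' channels), `"running_mean"` subtracts a centred moving average of length
#' `length_s` from each channel.
#'
#' @param rec An [eeg_recording()].
#' @param mode `"across_channels"` or `"running_mean"`.
#' @param length_s Moving-average length (seconds) for `"running_mean"`.
#' @return The corrected [eeg_recording()].
#' @export
remove_average <- function(rec, mode = c("across_channels", "running_mean"),
                           length_s = 1) {
  assert_that(inherits(rec, "eeg_recording"), "rec must be an eeg_recording")
  mode <- match.arg(mode)
  x <- rec$samples
  if (mode == "across_channels") {
    assert_that(ncol(x) >= 2,
                "across-channels average removal needs >= 2 channels")
    x <- x - rowMeans(x)
  } else {
    k <- max(1L, round(length_s * rec$fs))
    kern <- rep(1 / k, k)
    for (i in seq_len(ncol(x))) {
      mu <- stats::filter(x[, i], kern, sides = 2)
      mu[is.na(mu)] <- mean(x[, i])          # edges fall back to global mean
      x[, i] <- x[, i] - mu
    }
  }
  rec$samples <- x
  rec
}

# Forward-backward IIR filtering over reflect-padded data. The pad spans
# three time constants of the slowest (low-edge) pole so startup
# transients decay inside the pad, and the mean is removed first (the
# pass band excludes DC, and zero-state filtering of an offset otherwise
# rings at the low edge).
filtfilt_reflect <- function(flt, x, pad) {
  np <- min(pad, length(x) - 1L)
  mu <- mean(x)
  x <- x - mu
  pad_head <- 2 * x[1] - x[seq(np + 1, 2)]
  pad_tail <- 2 * x[length(x)] - x[seq(length(x) - 1, length(x) - np)]
  y <- c(pad_head, x, pad_tail)
  y <- signal::filter(flt, y)
  y <- rev(signal::filter(flt, rev(y)))
  y[seq(np + 1, np + length(x))]
}

#' Band-pass filter a recording
#'
#' Butterworth band-pass of the given order; in zero-phase mode the filter
#' runs forward and backward (no phase distortion, squared magnitude
#' response) over reflect-padded data. Pass-band sinusoid amplitudes are
#' preserved within 2 %; DC is removed.
#'
#' @param rec An [eeg_recording()].
#' @param low,high Band edges in Hz, `0 < low < high < fs/2`.
#' @param order Butterworth design order (default 4).
#' @param zero_phase Apply forward-backward (default `TRUE`).
#' @return The filtered [eeg_recording()].
#' @export
bandpass <- function(rec, low = 1, high = 20, order = 4, zero_phase = TRUE) {
  assert_that(inherits(rec, "eeg_recording"), "rec must be an eeg_recording")
  if (!(low > 0 && low < high && high < rec$fs / 2)) {
    stop_validation("band [", low, ", ", high, "] Hz must satisfy 0 < low < high < fs/2 = ",
                    rec$fs / 2)
  }
  flt <- signal::butter(order, c(low, high) / (rec$fs / 2), type = "pass")
  pad <- as.integer(round(3 * rec$fs / low))
  x <- rec$samples
  for (i in seq_len(ncol(x))) {
    x[, i] <- if (zero_phase) {
      filtfilt_reflect(flt, x[, i], pad)
    } else {
      as.numeric(signal::filter(flt, x[, i]))
    }
  }
  rec$samples <- x
  rec
}

#' Slice a recording into overlapped windows
#'
#' Window starts advance by `round(step_s * fs)` samples; window count is
#' `floor((duration - win_s)/step_s) + 1`. Times in seconds are
#' authoritative and carried with the windows.
#'
#' @param rec An [eeg_recording()].
#' @param plan A [window_plan()].
#' @return An object of class `eeg_windows`: `starts` (absolute start times,
#'   seconds), `win_s`, `fs`, `channel_labels`, and `segments`, a named list
#'   with one samples-x-windows matrix per channel. A recording shorter than
#'   one window yields zero windows with a warning.
#' @export
make_windows <- function(rec, plan = window_plan()) {
  assert_that(inherits(rec, "eeg_recording"), "rec must be an eeg_recording")
  assert_that(inherits(plan, "window_plan"), "plan must be a window_plan")
  n <- nrow(rec$samples)
  wlen <- round(plan$win_s * rec$fs)
  step <- round(plan$step_s * rec$fs)
  if (n < wlen) {
    warning("recording (", n / rec$fs, " s) shorter than one ", plan$win_s,
            " s window; returning zero windows")
    starts <- numeric(0)
  } else {
    nw <- (n - wlen) %/% step + 1
    starts <- (seq_len(nw) - 1) * step / rec$fs + rec$start_time
  }
  segs <- lapply(seq_len(ncol(rec$samples)), function(i) {
    if (!length(starts)) return(matrix(0, wlen, 0))
    idx <- outer(seq_len(wlen) - 1L, as.integer((seq_along(starts) - 1) * step),
                 `+`) + 1L
    matrix(rec$samples[, i][idx], nrow = wlen)
  })
  names(segs) <- rec$channel_labels
  structure(list(starts = starts, win_s = plan$win_s, step_s = plan$step_s,
                 fs = rec$fs, channel_labels = rec$channel_labels,
                 segments = segs),
            class = "eeg_windows")
}

#' @export
print.eeg_windows <- function(x, ...) {
  cat(sprintf("<eeg_windows> %d windows of %g s (step %g s) x %d channel(s) @ %g Hz\n",
              length(x$starts), x$win_s, x$step_s, length(x$segments), x$fs))
  invisible(x)
}

#' Mask artifact-contaminated windows
#'
#' A lightweight threshold policy suited to devices with few channels: a
#' window is masked when its peak absolute amplitude exceeds `max_abs_uV`
#' or its RMS exceeds `max_rms_ratio` times the running median window RMS
#' (the baseline). Kept windows are returned unchanged.
#'
#' @param windows An [make_windows()] result.
#' @param max_abs_uV Peak amplitude threshold (microvolts).
#' @param max_rms_ratio RMS ratio threshold versus the running baseline.
#' @param baseline_windows Baseline length (windows) for the running median.
#' @return List with `windows` (input, unchanged) and `mask`, a logical
#'   vector (`TRUE` = artifact) of length equal to the window count.
#' @export
reject_artifacts <- function(windows, max_abs_uV = 300, max_rms_ratio = 8,
                             baseline_windows = 60) {
  assert_that(inherits(windows, "eeg_windows"), "windows must be eeg_windows")
  nw <- length(windows$starts)
  mask <- rep(FALSE, nw)
  for (seg in windows$segments) {
    if (!nw) break
    peak <- apply(abs(seg), 2, max) * 1e6
    rms <- sqrt(colMeans(seg^2)) * 1e6
    base <- stats::runmed(rms, k = min(baseline_windows * 2 + 1,
                                       max(1, 2 * (nw %/% 2) - 1)))
    mask <- mask | peak > max_abs_uV | rms > max_rms_ratio * pmax(base, 1e-9)
  }
  list(windows = windows, mask = mask)
}
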