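# Dual-device acquisition agreement: DTW-aligned Pearson correlation,
# Welch periodogram comparison, and Bland-Altman analysis of PSD
# differences.

#' DTW-aligned Pearson correlation between two devices
#'
#' Compares one channel of two simultaneous recordings of the same
#' physiology. The second recording is first resampled to the reference
#' rate (polyphase band-limited resampling for rational rate ratios),
#' then residual timing differences are corrected by banded dynamic time
#' warping on z-scored segments (Sakoe-Chiba band, default 0.25 s);
#' warped duplicates are averaged per reference index so exactly one
#' aligned sample exists per time point, and the Pearson correlation of
#' the aligned pair is returned.
#'
#' @param a Reference [eeg_recording()].
#' @param b Second-device [eeg_recording()].
#' @param window_s Correlation window length in seconds (default 60),
#'   taken from the start of both recordings (trigger-synchronized
#'   origin).
#' @param channel Channel index or label (default 1).
#' @param band_s DTW band half-width in seconds.
#' @return Pearson correlation coefficient in `[-1, 1]`.
#' @export
align_and_correlate <- function(a, b, window_s = 60, channel = 1,
                                band_s = 0.25) {
  assert_that(inherits(a, "eeg_recording") && inherits(b, "eeg_recording"),
              "a and b must be eeg_recordings")
  if (window_s > duration_s(a) + 1e-9 || window_s > duration_s(b) + 1e-9) {
    stop_validation("window_s = ", window_s,
                    " s exceeds a recording (a: ", duration_s(a),
                    " s, b: ", duration_s(b), " s)")
  }
  xa <- a$samples[seq_len(round(window_s * a$fs)), channel]
  xb <- b$samples[seq_len(round(window_s * b$fs)), channel]
  if (abs(a$fs - b$fs) > 1e-9) {
    ratio <- a$fs / b$fs
    pq <- rational_approx(ratio)
    xb <- signal::resample(xb, pq[1], pq[2])
  }
  n <- min(length(xa), length(xb))
  xa <- xa[seq_len(n)]; xb <- xb[seq_len(n)]
  za <- as.numeric(scale(xa)); zb <- as.numeric(scale(xb))
  # DTW corrects timing, not polarity: warping an inverted copy toward the
  # reference would destroy the anticorrelation it should report. Align on
  # the sign-corrected copy and restore the sign afterwards.
  sgn <- sign(stats::cor(za, zb))
  if (!is.finite(sgn) || sgn == 0) sgn <- 1
  zb_aligned <- .dtw_align_band(za, sgn * zb,
                                band = max(1L, round(band_s * a$fs)))
  sgn * stats::cor(za, zb_aligned)
}

# Small-denominator rational approximation p/q of a rate ratio.
rational_approx <- function(x, max_den = 1024) {
  best <- c(1, 1); err <- Inf
  for (q in seq_len(max_den)) {
    p <- round(x * q)
    if (p < 1) next
    e <- abs(x - p / q)
    if (e < err - 1e-15) {
      best <- c(p, q); err <- e
      if (e < 1e-12) break
    }
  }
  best
}

#' Bland-Altman agreement of two PSD estimates
#'
#' Per-frequency-bin differences `d = a - b` against means
#' `(a + b)/2`, summarized by the mean difference (MD), its standard
#' deviation (SD), the limits of agreement `MD +/- 1.96 SD` (the 95 %
#' interval for normally distributed differences), and the fraction of
#' bins inside the limits.
#'
#' @param psd_a,psd_b [welch_psd()] results (or bare numeric vectors of
#'   equal length) on a common frequency grid.
#' @param log_power Compare `10*log10` power instead of raw power
#'   (default `FALSE`).
#' @return List of class `bland_altman`: `mean_difference`,
#'   `sd_difference`, `limits`, `fraction_inside`, `differences`, `means`.
#' @export
bland_altman <- function(psd_a, psd_b, log_power = FALSE) {
  va <- if (inherits(psd_a, "welch_psd")) psd_a$psd else as.numeric(psd_a)
  vb <- if (inherits(psd_b, "welch_psd")) psd_b$psd else as.numeric(psd_b)
  if (inherits(psd_a, "welch_psd") && inherits(psd_b, "welch_psd")) {
    if (length(psd_a$freq) != length(psd_b$freq) ||
        max(abs(psd_a$freq - psd_b$freq)) > 1e-9) {
      stop_validation("PSD frequency grids do not match")
    }
  }
  assert_that(length(va) == length(vb), "PSD vectors must share one grid")
  if (log_power) {
    va <- 10 * log10(va); vb <- 10 * log10(vb)
  }
  d <- va - vb
  m <- (va + vb) / 2
  md <- mean(d)
  sdd <- stats::sd(d)
  lims <- c(lower = md - 1.96 * sdd, upper = md + 1.96 * sdd)
  inside <- if (sdd > 0) mean(d >= lims[1] & d <= lims[2]) else 1
  structure(list(mean_difference = md, sd_difference = sdd, limits = lims,
                 fraction_inside = inside, differences = d, means = m),
            class = "bland_altman")
}

#' @export
print.bland_altman <- function(x, ...) {
  cat(sprintf("<bland_altman> MD=%.4g SD=%.4g limits=[%.4g, %.4g] inside=%.1f%%\n",
              x$mean_difference, x$sd_difference, x$limits[1], x$limits[2],
              100 * x$fraction_inside))
  invisible(x)
}

#' Full dual-device agreement report
#'
#' For each shared channel: the DTW-aligned Pearson correlation over
#' `window_s`, Welch PSDs of both devices over `span_s` (b's PSD computed
#' after resampling to a's rate so the grids coincide), and the
#' Bland-Altman summary of their difference.
#'
#' @param a,b Two [eeg_recording()]s of the same session.
#' @param window_s Correlation window (seconds, default 60).
#' @param span_s PSD span (seconds; default the full common span).
#' @param epoch_s Welch epoch length (seconds, default 4).
#' @return List of class `agreement_report` with per-channel entries
#'   (`pearson_r`, `psd_a`, `psd_b`, `bland_altman`).
#' @export
agreement_report <- function(a, b, window_s = 60, span_s = NULL,
                             epoch_s = 4) {
  chans <- intersect(a$channel_labels, b$channel_labels)
  assert_that(length(chans) >= 1, "recordings share no channel labels")
  span_s <- span_s %||% min(duration_s(a), duration_s(b))
  out <- lapply(chans, function(ch) {
    b_res <- if (abs(a$fs - b$fs) > 1e-9) {
      gen_dual_device(b, fs2 = a$fs)    # deterministic resample (no noise)
    } else {
      b
    }
    psd_a <- welch_psd(a, epoch_s = epoch_s, span_s = span_s, channel = ch)
    psd_b <- welch_psd(b_res, epoch_s = epoch_s,
                       span_s = min(span_s, duration_s(b_res)), channel = ch)
    list(pearson_r = align_and_correlate(a, b, window_s, channel = ch),
         psd_a = psd_a, psd_b = psd_b,
         bland_altman = bland_altman(psd_a, psd_b))
  })
  names(out) <- chans
  structure(out, class = "agreement_report")
}

#' @export
print.agreement_report <- function(x, ...) {
  for (ch in names(x)) {
    cat(sprintf("channel %s: r = %.4f, ", ch, x[[ch]]$pearson_r))
    print(x[[ch]]$bland_altman)
  }
  invisible(x)
}
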