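#' Welch power spectral density estimate
#'
#' Averaged modified periodogram: the signal is cut into epochs of
#' `epoch_s` seconds with fractional `overlap` (default 50 %), each epoch
#' is mean-removed, tapered (Hann by default), and its one-sided
#' periodogram accumulated. Scaling is power spectral density
#' (`unit^2/Hz`): the integral of the PSD over frequency matches the
#' time-domain variance (Parseval), up to taper-induced leakage.
#'
#' @param x Numeric vector, or an [eeg_recording()] (first channel taken
#'   unless `channel` given).
#' @param fs Sampling rate in Hz (ignored when `x` is a recording).
#' @param epoch_s Epoch length in seconds (default 4, giving a 0.25 Hz
#'   grid).
#' @param overlap Fractional epoch overlap in `[0, 1)`.
#' @param window Taper: `"hann"` or `"rect"`.
#' @param span_s Optional analysis span: only the first `span_s` seconds
#'   are used.
#' @param channel Channel label or index when `x` is a recording.
#' @return List of class `welch_psd` with `freq` (Hz) and `psd`
#'   (power/Hz), plus `fs`, `epoch_s`, `n_epochs`.
#' @export
welch_psd <- function(x, fs = NULL, epoch_s = 4, overlap = 0.5,
                      window = c("hann", "rect"), span_s = NULL,
                      channel = 1) {
  window <- match.arg(window)
  if (inherits(x, "eeg_recording")) {
    fs <- x$fs
    x <- x$samples[, channel]
  }
  assert_that(!is.null(fs) && fs > 0, "fs required for a bare vector")
  if (!is.null(span_s)) {
    assert_that(span_s * fs <= length(x) + 1e-9,
                "requested span exceeds the available signal")
    x <- x[seq_len(round(span_s * fs))]
  }
  nseg <- round(epoch_s * fs)
  if (length(x) < nseg) {
    stop_validation("signal (", length(x) / fs,
                    " s) shorter than one epoch (", epoch_s, " s)")
  }
  step <- max(1L, round(nseg * (1 - overlap)))
  starts <- seq(1L, length(x) - nseg + 1L, by = step)
  w <- if (window == "hann") {
    0.5 - 0.5 * cos(2 * pi * seq(0, nseg - 1) / (nseg - 1))
  } else {
    rep(1, nseg)
  }
  u <- sum(w^2)                              # taper power normalization
  nfreq <- nseg %/% 2 + 1
  acc <- numeric(nfreq)
  for (s in starts) {
    seg <- x[s:(s + nseg - 1)]
    seg <- (seg - mean(seg)) * w
    X <- stats::fft(seg)[seq_len(nfreq)]
    acc <- acc + (Mod(X)^2) / (fs * u)
  }
  psd <- acc / length(starts)
  # fold two-sided power into the one-sided estimate
  interior <- 2:(nfreq - if (nseg %% 2 == 0) 1 else 0)
  psd[interior] <- 2 * psd[interior]
  structure(list(freq = seq(0, nfreq - 1) * fs / nseg, psd = psd,
                 fs = fs, epoch_s = epoch_s, n_epochs = length(starts)),
            class = "welch_psd")
}

# Integrate a PSD over [lo, hi) Hz by the rectangle rule on the FFT grid.
band_power_from_psd <- function(psd, lo, hi) {
  df <- psd$freq[2] - psd$freq[1]
  sum(psd$psd[psd$freq >= lo & psd$freq < hi]) * df
}
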