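#' Synthetic EEG specification
#'
#' Parameters for the seeded generators that emulate every input class the
#' toolkit consumes: 1/f-like background with band oscillations, eye-closure
#' alpha synchronization, rhythmic ictal discharges, blink/movement
#' artifacts, and the quantization + Gaussian noise floor of a 24-bit
#' front end. Identical specs (seed included) produce bit-identical output.
#'
#' @param fs Sampling rate (Hz). Default 64 Hz: the detection pipeline
#'   analyses a [1, 20] Hz band, so a 32 Hz Nyquist retains all
#'   discriminative content at a quarter of the arithmetic cost of clinical
#'   rates.
#' @param duration_s Record duration (seconds).
#' @param channels Channel labels for generated recordings.
#' @param background List: `slope` (power-law exponent of the 1/f^slope
#'   spectrum), `rms_uV` (total background RMS, microvolts), `oscillations`
#'   (list of `c(freq_hz, amp_uV)` sinusoids).
#' @param alpha List: `center_hz`, `amp_uV`, `closures` (list of
#'   `c(onset_s, offset_s)` eye-closure intervals).
#' @param seizures Data frame with columns `onset_s`, `duration_s`,
#'   `freq_hz`, `amp_uV` (one rhythmic discharge per row).
#' @param artifacts List: `blink_rate_per_min`, `blink_amp_uV`,
#'   `blink_channels` (labels receiving ocular artifacts).
#' @param noise_rms_uV Additive Gaussian sensor-noise RMS (microvolts).
#' @param acquisition Optional [acquisition_spec()] used by
#'   [gen_noise_floor()] for quantization.
#' @param seed Master integer seed.
#' @return An object of class `synth_spec`.
#' @export
synth_spec <- function(fs = 64, duration_s = 60,
                       channels = c("F7T7", "F8T8"),
                       background = list(slope = 1, rms_uV = 20,
                                         oscillations = list()),
                       alpha = list(center_hz = 10, amp_uV = 20,
                                    closures = list()),
                       seizures = NULL,
                       artifacts = list(blink_rate_per_min = 0,
                                        blink_amp_uV = 150,
                                        blink_channels = "F7T7"),
                       noise_rms_uV = 0.5,
                       acquisition = acquisition_spec(),
                       seed = 1L) {
  assert_that(duration_s > 0, "duration_s must be positive")
  assert_that(fs > 0, "fs must be positive")
  if (!is.null(seizures)) {
    seizures <- as.data.frame(seizures)
    assert_that(all(c("onset_s", "duration_s", "freq_hz", "amp_uV") %in%
                      names(seizures)), "seizures needs onset_s/duration_s/freq_hz/amp_uV")
    if (any(seizures$onset_s < 0 |
            seizures$onset_s + seizures$duration_s > duration_s)) {
      stop_validation("seizure interval outside [0, duration_s]")
    }
  }
  amps <- c(background$rms_uV, alpha$amp_uV, noise_rms_uV,
            artifacts$blink_amp_uV %||% 0)
  assert_that(all(amps >= 0), "all amplitudes must be >= 0")
  structure(list(fs = fs, duration_s = duration_s, channels = channels,
                 background = background, alpha = alpha, seizures = seizures,
                 artifacts = artifacts, noise_rms_uV = noise_rms_uV,
                 acquisition = acquisition, seed = as.integer(seed)),
            class = "synth_spec")
}

# 1/f^slope coloured noise of unit RMS, via spectral shaping of white noise.
colored_noise <- function(n, fs, slope) {
  w <- stats::rnorm(n)
  if (slope == 0) return(w / stats::sd(w))
  X <- stats::fft(w)
  f <- c(0, seq_len(n - 1)) * fs / n
  f <- pmin(f, fs - f)                      # two-sided frequency magnitude
  shape <- c(0, 1 / f[-1]^(slope / 2))      # kill DC, shape the rest
  x <- Re(stats::fft(X * shape, inverse = TRUE)) / n
  x / sqrt(mean(x^2))
}

synth_background_channel <- function(spec) {
  n <- round(spec$duration_s * spec$fs)
  bg <- spec$background
  x <- numeric(n)
  if ((bg$rms_uV %||% 0) > 0) {
    x <- colored_noise(n, spec$fs, bg$slope %||% 1) * bg$rms_uV
  }
  tm <- (seq_len(n) - 1) / spec$fs
  for (osc in bg$oscillations %||% list()) {
    x <- x + osc[2] * sin(2 * pi * osc[1] * tm + stats::runif(1, 0, 2 * pi))
  }
  if (spec$noise_rms_uV > 0) x <- x + stats::rnorm(n, sd = spec$noise_rms_uV)
  x
}

#' Generate background EEG
#'
#' Channels of 1/f^slope coloured noise plus any configured sinusoidal
#' oscillations and sensor noise; the event list is empty.
#'
#' @param spec A [synth_spec()].
#' @return An [eeg_recording()] (volts, bipolar montage).
#' @export
gen_background <- function(spec) {
  assert_that(inherits(spec, "synth_spec"), "spec must be a synth_spec")
  with_seed(spec$seed, {
    x <- vapply(seq_along(spec$channels),
                function(i) synth_background_channel(spec),
                numeric(round(spec$duration_s * spec$fs)))
    eeg_recording(x * 1e-6, spec$fs, spec$channels, montage = "bipolar")
  })
}

#' Generate an eyes-open/eyes-closed alpha session
#'
#' Background EEG plus an alpha-band sinusoid (default 10 Hz) active only
#' during the configured eye-closure intervals, which are annotated as
#' `"eyes_closed"` events. A centre frequency outside the conventional
#' [8, 12] Hz alpha band raises a warning, not an error.
#'
#' @param spec A [synth_spec()].
#' @return An [eeg_recording()] with eye-closure events.
#' @export
gen_alpha_session <- function(spec) {
  assert_that(inherits(spec, "synth_spec"), "spec must be a synth_spec")
  al <- spec$alpha
  if (al$center_hz < 8 || al$center_hz > 12) {
    warning("alpha centre ", al$center_hz, " Hz lies outside the [8, 12] Hz band")
  }
  with_seed(spec$seed, {
    n <- round(spec$duration_s * spec$fs)
    tm <- (seq_len(n) - 1) / spec$fs
    gate <- rep(FALSE, n)
    closures <- al$closures %||% list()
    for (cl in closures) gate <- gate | (tm >= cl[1] & tm < cl[2])
    x <- vapply(seq_along(spec$channels), function(i) {
      ch <- synth_background_channel(spec)
      ch + ifelse(gate, al$amp_uV * sin(2 * pi * al$center_hz * tm +
                                          stats::runif(1, 0, 2 * pi)), 0)
    }, numeric(n))
    ev <- if (length(closures)) {
      event_list(vapply(closures, `[`, 0, 1), vapply(closures, `[`, 0, 2),
                 label = "eyes_closed")
    } else {
      event_list()
    }
    eeg_recording(x * 1e-6, spec$fs, spec$channels, montage = "bipolar",
                  events = ev)
  })
}

# Rhythmic ictal discharge: amplitude-modulated sinusoid with a linear
# downward frequency chirp plus a first harmonic; a short attack ramp over
# the first 10 % of the event gives the amplitude build-up.
ictal_waveform <- function(tm_rel, dur, freq, amp, phase = 0) {
  f1 <- freq * (1 - 0.25 * tm_rel / dur)      # e.g. 4 Hz -> 3 Hz chirp
  ph <- 2 * pi * cumsum(f1) * (tm_rel[2] - tm_rel[1])
  env <- pmin(tm_rel / (0.1 * dur), 1)
  amp * env * (sin(ph + phase) + 0.6 * sin(2 * ph + phase))
}

#' Generate an annotated seizure dataset
#'
#' Each record is background EEG with rhythmic high-amplitude discharges
#' superimposed over the annotated ictal intervals (identically on every
#' channel, as frontotemporal discharges project to both derivations), plus
#' optional blink artifacts. Per-record seeds are derived as
#' `seed + record index`, so records are independent yet reproducible.
#'
#' @param spec A [synth_spec()] whose `seizures` table describes the
#'   per-record discharges (recycled across records if a single table).
#' @param n_records Number of records to generate.
#' @param seizure_table Optional list of per-record seizure tables
#'   overriding `spec$seizures`.
#' @return List of [eeg_recording()]s, each annotated with its seizures.
#' @export
gen_seizure_dataset <- function(spec, n_records = 1, seizure_table = NULL) {
  assert_that(inherits(spec, "synth_spec"), "spec must be a synth_spec")
  lapply(seq_len(n_records), function(r) {
    sz <- if (!is.null(seizure_table)) seizure_table[[r]] else spec$seizures
    rspec <- spec
    rspec$seed <- spec$seed + r
    rspec$seizures <- NULL
    rec <- with_seed(rspec$seed, {
      n <- round(spec$duration_s * spec$fs)
      tm <- (seq_len(n) - 1) / spec$fs
      x <- vapply(seq_along(spec$channels),
                  function(i) synth_background_channel(rspec), numeric(n))
      if (!is.null(sz) && nrow(sz)) {
        if (any(sz$duration_s > spec$duration_s)) {
          stop_validation("seizure longer than record")
        }
        for (k in seq_len(nrow(sz))) {
          idx <- which(tm >= sz$onset_s[k] &
                         tm < sz$onset_s[k] + sz$duration_s[k])
          wav <- ictal_waveform(tm[idx] - sz$onset_s[k], sz$duration_s[k],
                                sz$freq_hz[k], sz$amp_uV[k])
          x[idx, ] <- x[idx, ] + wav
        }
      }
      blinks <- blink_artifact(rspec, tm)
      if (!is.null(blinks)) {
        for (chn in intersect(rspec$artifacts$blink_channels %||% character(),
                              spec$channels)) {
          x[, match(chn, spec$channels)] <- x[, match(chn, spec$channels)] + blinks
        }
      }
      ev <- if (!is.null(sz) && nrow(sz)) {
        event_list(sz$onset_s, sz$onset_s + sz$duration_s, "seizure")
      } else {
        event_list()
      }
      eeg_recording(x * 1e-6, spec$fs, spec$channels, montage = "bipolar",
                    events = ev)
    })
    rec
  })
}

# Biphasic low-frequency (<4 Hz) blink pulses at Poisson times.
blink_artifact <- function(spec, tm) {
  rate <- spec$artifacts$blink_rate_per_min %||% 0
  if (rate <= 0) return(NULL)
  n_blinks <- stats::rpois(1, rate * spec$duration_s / 60)
  if (n_blinks == 0) return(numeric(length(tm)))
  centers <- sort(stats::runif(n_blinks, 0, spec$duration_s))
  amp <- spec$artifacts$blink_amp_uV %||% 150
  x <- numeric(length(tm))
  for (cc in centers) {
    u <- (tm - cc) / 0.35                      # ~0.7 s biphasic pulse
    x <- x + amp * u * exp(0.5 - 2 * u^2) * 2  # derivative-of-Gaussian shape
  }
  x
}

#' View the same physiology through a second device
#'
#' Produces a second-device observation of a recording: resampled to `fs2`
#' by linear interpolation on a time grid delayed by `jitter_s`, scaled by
#' `gain2`, with additive Gaussian noise. Used to exercise the agreement
#' module with a known shared source.
#'
#' @param rec The reference [eeg_recording()].
#' @param fs2 Second device's sampling rate (Hz), > 0.
#' @param jitter_s Acquisition delay (seconds).
#' @param gain2 Amplitude scale of the second device.
#' @param noise2_uV Additive noise RMS (microvolts).
#' @param seed Seed for the added noise.
#' @return An [eeg_recording()] at `fs2` covering the same span.
#' @export
gen_dual_device <- function(rec, fs2 = rec$fs, jitter_s = 0, gain2 = 1,
                            noise2_uV = 0, seed = 1L) {
  assert_that(inherits(rec, "eeg_recording"), "rec must be an eeg_recording")
  if (fs2 <= 0) stop_validation("fs2 must be positive")
  t_in <- (seq_len(nrow(rec$samples)) - 1) / rec$fs
  t_out <- seq(0, duration_s(rec) - 1 / fs2, by = 1 / fs2)
  with_seed(seed, {
    x <- vapply(seq_len(ncol(rec$samples)), function(i) {
      y <- stats::approx(t_in, rec$samples[, i], xout = t_out + jitter_s,
                         rule = 2)$y * gain2
      if (noise2_uV > 0) y <- y + stats::rnorm(length(y), sd = noise2_uV * 1e-6)
      y
    }, numeric(length(t_out)))
    eeg_recording(x, fs2, rec$channel_labels, montage = rec$montage,
                  events = rec$events)
  })
}

#' Generate a shorted-input noise-floor stream
#'
#' Zero-mean Gaussian samples at the configured RMS, quantized at the
#' acquisition spec's per-bit resolution -- the bench condition for
#' input-referred-noise estimation. Warns when fewer than 10,000 samples
#' are produced, the customary minimum for a stable noise estimate.
#'
#' @param spec A [synth_spec()]; `noise_rms_uV` sets the underlying RMS and
#'   `acquisition` the quantizer.
#' @return A single-channel [eeg_recording()] labelled `"SHORT"`.
#' @export
gen_noise_floor <- function(spec) {
  assert_that(inherits(spec, "synth_spec"), "spec must be a synth_spec")
  n <- round(spec$duration_s * spec$fs)
  if (n < 10000) {
    warning("only ", n, " samples generated; noise estimates are customarily ",
            "taken over at least 10,000 consecutive samples")
  }
  with_seed(spec$seed, {
    x <- if (spec$noise_rms_uV > 0) {
      stats::rnorm(n, sd = spec$noise_rms_uV * 1e-6)
    } else {
      numeric(n)
    }
    step <- spec$acquisition$resolution_v
    x <- round(x / step) * step
    eeg_recording(x, spec$fs, "SHORT", montage = "referential")
  })
}
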