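# Acquisition-quality mathematics: input-referred noise, dynamic range,
# noise-free bits, effective number of bits, CMRR, and the IFCN clinical
# digital-EEG compliance check.

#' Input-referred noise, RMS
#'
#' Root of the mean squared amplitude of a shorted-input stream. Shorted
#' inputs may carry a DC offset that is not noise, so the sample mean is
#' removed by default; `remove_dc = FALSE` squares the raw samples (the
#' literal textbook definition). The result is in the unit of the input.
#'
#' @param samples Numeric vector (>= 2 samples); a warning is issued below
#'   10,000 samples, the customary minimum for a stable estimate.
#' @param remove_dc Subtract the sample mean first (default `TRUE`).
#' @return RMS noise in the input unit.
#' @export
irn_rms <- function(samples, remove_dc = TRUE) {
  if (!length(samples)) stop_validation("empty input stream")
  assert_that(length(samples) >= 2, "need at least 2 samples")
  if (length(samples) < 10000) {
    warning("IRN estimated from ", length(samples),
            " samples; at least 10,000 consecutive samples are recommended")
  }
  if (remove_dc) samples <- samples - mean(samples)
  sqrt(mean(samples^2))
}

#' Peak-to-peak noise from RMS
#'
#' The crest-factor convention for Gaussian noise: peak-to-peak is taken
#' as 6.6 times the RMS (+/- 3.3 sigma covers ~99.9 % of samples).
#'
#' @param irn_rms RMS noise (any unit), >= 0.
#' @return `6.6 * irn_rms` in the same unit.
#' @export
irn_pp <- function(irn_rms) {
  if (any(irn_rms < 0)) stop_validation("RMS noise must be non-negative")
  6.6 * irn_rms
}

#' Dynamic range of the acquisition chain
#'
#' `20 * log10(vref / (sqrt(2) * gain * irn_rms))` dB: the ratio of the
#' full-scale RMS sine to the input-referred noise floor.
#'
#' @param vref Reference voltage (V).
#' @param gain Amplifier gain (V/V).
#' @param irn_rms RMS input-referred noise (V).
#' @return Dynamic range in dB (`Inf` for zero noise).
#' @export
dynamic_range <- function(vref, gain, irn_rms) {
  assert_that(vref > 0 && gain > 0 && irn_rms >= 0,
              "vref, gain must be positive; irn_rms non-negative")
  if (irn_rms == 0) return(Inf)
  20 * log10(vref / (sqrt(2) * gain * irn_rms))
}

#' Effective number of bits
#'
#' `log2(vref / (sqrt(2) * gain * v_rms))`: converter resolution
#' discounted by the RMS noise floor. Halving the noise gains exactly one
#' bit; `enob = dr / (20*log10(2))` for identical inputs.
#'
#' @param vref Reference voltage (V).
#' @param gain Amplifier gain (V/V).
#' @param v_rms RMS noise (V).
#' @return Effective bits (`Inf` for zero noise).
#' @export
enob <- function(vref, gain, v_rms) {
  assert_that(vref > 0 && gain > 0 && v_rms >= 0,
              "vref, gain must be positive; v_rms non-negative")
  if (v_rms == 0) return(Inf)
  log2(vref / (sqrt(2) * gain * v_rms))
}

#' Noise-free bits
#'
#' Resolution discounted by the peak-to-peak noise:
#' `log2(2 * vref / (gain * irn_pp))` (the full differential input span
#' over the peak-to-peak noise). A formula dialect with an extra
#' `sqrt(2)` circulates in print, but it does not reproduce published
#' front-end figures, whereas this span form does; `dialect = "sqrt2"`
#' exposes the alternative for comparison.
#'
#' @param vref Reference voltage (V).
#' @param gain Amplifier gain (V/V).
#' @param irn_pp Peak-to-peak input-referred noise (V).
#' @param dialect `"span"` (default) or `"sqrt2"`.
#' @return Noise-free bits (`Inf` for zero noise).
#' @export
noise_free_bits <- function(vref, gain, irn_pp, dialect = c("span", "sqrt2")) {
  dialect <- match.arg(dialect)
  assert_that(vref > 0 && gain > 0 && irn_pp >= 0,
              "vref, gain must be positive; irn_pp non-negative")
  if (irn_pp == 0) return(Inf)
  if (dialect == "span") {
    log2(2 * vref / (gain * irn_pp))
  } else {
    log2(vref / (sqrt(2) * gain * irn_pp))
  }
}

#' Full noise report for one acquisition configuration
#'
#' Runs the characterization chain on a shorted-input stream: RMS and
#' peak-to-peak input-referred noise, dynamic range, noise-free bits, and
#' effective number of bits.
#'
#' @param samples Shorted-input stream in volts (an [eeg_recording()]'s
#'   first channel, or a bare numeric vector).
#' @param spec An [acquisition_spec()].
#' @param bandwidth Annotated analysis bandwidth `c(lo, hi)` Hz (metadata;
#'   the stream is assumed already band-limited as acquired).
#' @param remove_dc Passed to [irn_rms()].
#' @return List of class `noise_report`: `irn_rms_uV`, `irn_pp_uV`,
#'   `dr_db`, `nfb_bits`, `enob_bits`, `n_samples`, `bandwidth`, `spec`.
#' @export
noise_report <- function(samples, spec = acquisition_spec(),
                         bandwidth = c(0.5, 100), remove_dc = TRUE) {
  if (inherits(samples, "eeg_recording")) samples <- samples$samples[, 1]
  rms_v <- irn_rms(samples, remove_dc = remove_dc)
  pp_v <- irn_pp(rms_v)
  structure(list(irn_rms_uV = rms_v * 1e6, irn_pp_uV = pp_v * 1e6,
                 dr_db = dynamic_range(spec$vref, spec$pga_gain, rms_v),
                 nfb_bits = noise_free_bits(spec$vref, spec$pga_gain, pp_v),
                 enob_bits = enob(spec$vref, spec$pga_gain, rms_v),
                 n_samples = length(samples), bandwidth = bandwidth,
                 spec = spec),
            class = "noise_report")
}

#' @export
print.noise_report <- function(x, ...) {
  cat(sprintf("<noise_report> IRN %.3g uVrms / %.3g uVpp | DR %.2f dB | NFB %.2f | ENOB %.2f (n=%d)\n",
              x$irn_rms_uV, x$irn_pp_uV, x$dr_db, x$nfb_bits, x$enob_bits,
              x$n_samples))
  invisible(x)
}

# Amplitude of a sinusoid at a target frequency, estimated from a
# flat-top-windowed DFT with a 3-bin energy sum (amplitude-accurate even
# when the tone straddles bins).
dft_amplitude <- function(x, fs, freq) {
  n <- length(x)
  if (freq < 2 * fs / n || freq > fs / 2) {
    stop_validation("test frequency ", freq,
                    " Hz not resolvable from ", n, " samples at ", fs, " Hz")
  }
  k <- seq(0, n - 1)
  # 5-term flat-top window (amplitude-flat main lobe)
  a <- c(0.21557895, 0.41663158, 0.277263158, 0.083578947, 0.006947368)
  w <- a[1] - a[2] * cos(2 * pi * k / (n - 1)) +
    a[3] * cos(4 * pi * k / (n - 1)) - a[4] * cos(6 * pi * k / (n - 1)) +
    a[5] * cos(8 * pi * k / (n - 1))
  X <- stats::fft((x - mean(x)) * w)
  kgrid <- seq(2, n %/% 2)
  near <- kgrid[abs((kgrid - 1) * fs / n - freq) <= 2 * fs / n]
  peak <- near[which.max(Mod(X[near]))]
  bins <- max(2, peak - 1):min(n %/% 2, peak + 1)
  amp2 <- sum(Mod(X[bins])^2)
  # For a bin-centred tone the 3 central bins hold (A/2)^2 * R * W0^2 of
  # energy, with R the window's 3-bin-to-peak energy ratio; the flat-top
  # main lobe keeps this recovery amplitude-accurate off-centre too.
  W <- Mod(stats::fft(w))
  R <- sum(W[c(n, 1, 2)]^2) / W[1]^2
  2 * sqrt(amp2 / R) / sum(w)
}

#' Common-mode rejection ratio from a bench stream
#'
#' A common-mode sinusoid of known peak amplitude `vin_p` is applied to
#' all inputs; the residual at the test frequency in the (input-referred)
#' output stream is estimated from a flat-top-windowed DFT with a 3-bin
#' energy sum. The ratio is reported as positive rejection,
#' `20 * log10(vin_p / vout_p)` dB.
#'
#' @param stream Output samples in volts (input-referred; pass `gain` if
#'   not yet divided out). At least 2 minutes of data are customary; a
#'   shorter stream warns.
#' @param vin_p Applied common-mode peak amplitude (V), > 0.
#' @param test_freq Test frequency (Hz), conventionally mains (50 Hz).
#' @param fs Sampling rate (Hz).
#' @param gain Amplifier gain still present in the stream (default 1).
#' @return List of class `cmrr_result`: `cmrr_db`, `test_freq`, `vin_p`,
#'   `vout_inref_p`.
#' @export
cmrr <- function(stream, vin_p, test_freq = 50, fs, gain = 1) {
  if (inherits(stream, "eeg_recording")) {
    fs <- stream$fs
    stream <- stream$samples[, 1]
  }
  assert_that(vin_p > 0, "vin_p must be positive")
  if (length(stream) < 120 * fs) {
    warning("CMRR stream is ", round(length(stream) / fs, 1),
            " s; at least 2 minutes are customary")
  }
  vout <- dft_amplitude(stream / gain, fs, test_freq)
  structure(list(cmrr_db = 20 * log10(vin_p / vout), test_freq = test_freq,
                 vin_p = vin_p, vout_inref_p = vout),
            class = "cmrr_result")
}

#' CMRR from known amplitudes
#'
#' The closed-form ratio when the residual amplitude is already known:
#' `20 * log10(vin_p / vout_inref_p)`, positive for rejection.
#'
#' @param vin_p Applied common-mode peak (V).
#' @param vout_inref_p Input-referred residual peak (V).
#' @return CMRR in dB.
#' @export
cmrr_db <- function(vin_p, vout_inref_p) {
  assert_that(vin_p > 0 && vout_inref_p > 0, "amplitudes must be positive")
  20 * log10(vin_p / vout_inref_p)
}

#' IFCN digital-EEG compliance check
#'
#' Evaluates the clinical-EEG acquisition guidelines: sampling rate >= 200
#' Hz, resolution <= 0.5 uV/bit, input impedance >= 100 MOhm, CMRR >= 110
#' dB at the amplifier input, and input-referred noise <= 1.5 uV
#' peak-to-peak over 0.5-100 Hz. Bounds are inclusive. A guideline whose
#' measurement is missing (`NA`) is marked not-evaluated and the overall
#' verdict becomes indeterminate (`NA`).
#'
#' @param fs Sampling rate (Hz).
#' @param resolution_uV Converter resolution (uV/bit).
#' @param impedance_mohm Input impedance (MOhm).
#' @param cmrr_db CMRR at the amplifier input (dB).
#' @param irn_pp_uV Peak-to-peak input-referred noise (uV).
#' @return Data frame of class `ifcn_check` with one row per guideline
#'   (`name`, `required`, `measured`, `pass`) and an `overall` attribute.
#' @export
ifcn_check <- function(fs, resolution_uV, impedance_mohm, cmrr_db,
                       irn_pp_uV) {
  rows <- data.frame(
    name = c("sampling_rate_hz", "resolution_uV_per_bit", "impedance_mohm",
             "cmrr_db", "irn_pp_uV"),
    required = c(">= 200", "<= 0.5", ">= 100", ">= 110", "<= 1.5"),
    measured = c(fs, resolution_uV, impedance_mohm, cmrr_db, irn_pp_uV),
    stringsAsFactors = FALSE)
  rows$pass <- c(fs >= 200, resolution_uV <= 0.5, impedance_mohm >= 100,
                 cmrr_db >= 110, irn_pp_uV <= 1.5)
  overall <- if (anyNA(rows$pass)) NA else all(rows$pass)
  structure(rows, overall = overall, class = c("ifcn_check", "data.frame"))
}

#' @export
print.ifcn_check <- function(x, ...) {
  cat("<ifcn_check> overall:",
      if (is.na(attr(x, "overall"))) "indeterminate"
      else if (attr(x, "overall")) "PASS" else "FAIL", "\n")
  print.data.frame(x, row.names = FALSE)
  invisible(x)
}
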