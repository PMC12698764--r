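# Published reference figures used as inputs for metric arithmetic and
# for cross-checking the characterization formulas. Values are transcribed
# from the benchmark write-up of the glasses-form-factor EEG platform this
# toolkit models: per-subject event scores on the 24-subject pediatric
# scalp-EEG corpus (CHB-MIT), workload-classification scores, and the
# front-end noise table.

#' Reported per-subject seizure-detection scores (CHB-MIT benchmark)
#'
#' The published per-subject sensitivity, precision, F1 and false-alarm
#' rate (per day) for the two-channel (glasses) and 18-channel (full-cap)
#' configurations, with each subject's total and tested seizure counts.
#' These are reference values for metric arithmetic - macro-averages and
#' F1/Gmean recomputation - not outputs of this package's pipeline.
#'
#' @param config `"glasses"` (two bipolar frontotemporal channels) or
#'   `"fullcap"` (18 channels).
#' @return Data frame with columns `subject`, `n_seizures`, `n_test`,
#'   `sens`, `prec`, `f1`, `far_per_day`.
#' @export
reported_seizure_scores <- function(config = c("glasses", "fullcap")) {
  config <- match.arg(config)
  subject <- sprintf("%02d", 1:24)
  n_seizures <- c(7, 3, 7, 4, 5, 10, 3, 5, 4, 7, 3, 27, 12, 8, 20, 10, 3,
                  6, 3, 8, 4, 3, 7, 16)
  n_test <- c(5, 2, 3, 3, 4, 7, 2, 3, 3, 6, 2, 16, 11, 4, 19, 9, 1, 5, 2,
              7, 3, 2, 4, 9)
  if (config == "glasses") {
    sens <- c(1.00, 0.50, 1.00, 0.33, 1.00, 0.00, 0.50, 1.00, 1.00, 1.00,
              1.00, 0.94, 0.27, 0.25, 0.68, 0.00, 0.00, 0.40, 1.00, 0.43,
              0.00, 1.00, 1.00, 1.00)
    prec <- c(0.38, 1.00, 0.75, 0.50, 0.50, 0.00, 1.00, 0.50, 1.00, 1.00,
              1.00, 0.63, 1.00, 1.00, 0.76, 0.00, 0.00, 1.00, 1.00, 0.60,
              0.00, 0.67, 0.80, 0.53)
    f1 <- c(0.56, 0.67, 0.86, 0.40, 0.67, 0.00, 0.67, 0.67, 1.00, 1.00,
            1.00, 0.75, 0.43, 0.40, 0.72, 0.00, 0.00, 0.57, 1.00, 0.50,
            0.00, 0.80, 0.89, 0.69)
    far <- c(5.41, 0.00, 0.73, 0.17, 2.91, 0.00, 0.00, 4.80, 0.00, 0.00,
             0.00, 14.4, 0.00, 0.00, 2.83, 0.00, 6.00, 0.00, 0.00, 2.73,
             1.74, 1.72, 1.15, 11.8)
  } else {
    sens <- c(1.00, 1.00, 1.00, 0.67, 1.00, 0.29, 0.50, 1.00, 1.00, 1.00,
              1.00, 0.94, 0.27, 1.00, 0.84, 0.00, 1.00, 0.40, 1.00, 1.00,
              0.33, 1.00, 1.00, 1.00)
    prec <- c(0.63, 0.50, 0.75, 0.67, 0.80, 0.67, 1.00, 0.43, 1.00, 1.00,
              1.00, 0.68, 0.75, 0.80, 0.80, 0.00, 0.50, 1.00, 1.00, 0.70,
              1.00, 1.00, 0.67, 0.69)
    f1 <- c(0.77, 0.67, 0.86, 0.67, 0.89, 0.40, 0.67, 0.60, 1.00, 1.00,
            1.00, 0.79, 0.40, 0.89, 0.82, 0.00, 0.67, 0.57, 1.00, 0.82,
            0.50, 1.00, 0.80, 0.82)
    far <- c(2.03, 2.40, 0.73, 0.17, 0.73, 0.41, 0.00, 6.40, 0.00, 0.00,
             0.00, 11.2, 1.50, 1.14, 2.83, 0.00, 1.50, 0.00, 0.00, 4.10,
             0.00, 0.00, 2.30, 5.90)
  }
  data.frame(subject = subject, n_seizures = n_seizures, n_test = n_test,
             sens = sens, prec = prec, f1 = f1, far_per_day = far,
             stringsAsFactors = FALSE)
}

#' Reported workload-classification test scores
#'
#' Published testing sensitivity, specificity, accuracy and Gmean (all
#' percent) for the two device configurations, used to check the scoring
#' arithmetic (and which of the two circulating Gmean formula dialects the
#' published numbers obey).
#'
#' @return Data frame with columns `config`, `sens`, `spec`, `acc`,
#'   `gmean`.
#' @export
reported_cwm_scores <- function() {
  data.frame(config = c("glasses", "fullcap"),
             sens = c(82.9, 73.3), spec = c(66.1, 87.7),
             acc = c(74.5, 80.5), gmean = c(74.0, 80.2),
             stringsAsFactors = FALSE)
}

#' Reported front-end noise figures
#'
#' The static-noise table for the 24-bit EEG front end at gain 24 V/V and
#' 250 Hz: measured (device) and datasheet rows of IRN (uVrms and uVpp),
#' noise-free bits, effective number of bits, and dynamic range.
#'
#' @return Data frame with columns `row`, `irn_rms_uV`, `irn_pp_uV`,
#'   `nfb_bits`, `enob_bits`, `dr_db`.
#' @export
reported_noise_table <- function() {
  data.frame(row = c("device", "datasheet"),
             irn_rms_uV = c(0.16, 0.14), irn_pp_uV = c(1.07, 0.98),
             nfb_bits = c(18.41, 18.54), enob_bits = c(19.64, 19.85),
             dr_db = c(118.24, 119.5),
             stringsAsFactors = FALSE)
}

#' Reported IFCN-comparison row for the device
#'
#' The measured acquisition figures entered into the clinical-guideline
#' comparison: 250 Hz sampling, 0.023 uV/bit resolution, > 1000 MOhm
#' input impedance, 110 dB CMRR (amplifier input), 1.07 uVpp noise.
#'
#' @return Named list of the five measured values.
#' @export
reported_ifcn_row <- function() {
  list(fs = 250, resolution_uV = 0.023, impedance_mohm = 1000,
       cmrr_db = 110, irn_pp_uV = 1.07)
}
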