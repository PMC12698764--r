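#' Multichannel EEG recording
#'
#' The central container of the toolkit: a uniformly sampled multichannel
#' signal with 10-20 channel labels, a sampling rate, a montage kind, and an
#' annotated [event_list()]. Amplitudes are stored in volts throughout; use
#' microvolts only at presentation (a single internal unit avoids silent
#' 1e6 scale errors between the characterization and EEG code paths).
#'
#' @param samples Numeric matrix, samples x channels (a plain vector is
#'   treated as one channel), amplitudes in volts.
#' @param fs Sampling rate in Hz, > 0.
#' @param channel_labels Character vector of unique channel names
#'   (e.g. `"F7"`, or `"F7T7"` for a bipolar derivation).
#' @param montage `"referential"` or `"bipolar"`.
#' @param start_time Seconds since session origin (default 0).
#' @param events An [event_list()] of annotations (default empty).
#' @return An object of class `eeg_recording`.
#' @export
eeg_recording <- function(samples, fs, channel_labels = NULL,
                          montage = c("referential", "bipolar"),
                          start_time = 0, events = event_list()) {
  if (is.vector(samples)) samples <- matrix(samples, ncol = 1)
  samples <- as.matrix(samples)
  storage.mode(samples) <- "double"
  assert_that(is.numeric(fs) && length(fs) == 1 && fs > 0, "fs must be > 0")
  montage <- match.arg(montage)
  if (is.null(channel_labels)) {
    channel_labels <- colnames(samples) %||% paste0("CH", seq_len(ncol(samples)))
  }
  channel_labels <- normalize_channel_label(channel_labels)
  assert_that(length(channel_labels) == ncol(samples),
              "need one label per channel")
  assert_that(!anyDuplicated(channel_labels), "channel labels must be unique")
  colnames(samples) <- channel_labels
  structure(list(samples = samples, fs = fs,
                 channel_labels = channel_labels, montage = montage,
                 start_time = start_time, events = events),
            class = "eeg_recording")
}

#' Normalize 10-20 channel labels
#'
#' Uppercases, strips whitespace, and rewrites bipolar pair labels such as
#' `"F7-T7"` or `"f7 - t7"` to the compact `"F7T7"` form. Labels in public
#' corpora vary in case and spacing; normalizing once keeps lookups exact.
#'
#' @param labels Character vector of raw labels.
#' @return Character vector of normalized labels.
#' @export
normalize_channel_label <- function(labels) {
  x <- toupper(gsub("[[:space:]]", "", as.character(labels)))
  gsub("^([A-Z]{1,2}[0-9Z]{1,2})-([A-Z]{1,2}[0-9Z]{1,2})$", "\\1\\2", x)
}

#' @export
print.eeg_recording <- function(x, ...) {
  cat(sprintf("<eeg_recording> %d ch x %.1f s @ %g Hz (%s montage), %d event(s)\n",
              ncol(x$samples), nrow(x$samples) / x$fs, x$fs, x$montage,
              n_events(x$events)))
  cat("  channels:", paste(x$channel_labels, collapse = ", "), "\n")
  invisible(x)
}

#' @export
as.data.frame.eeg_recording <- function(x, ...) {
  data.frame(time = (seq_len(nrow(x$samples)) - 1) / x$fs + x$start_time,
             x$samples, check.names = FALSE)
}

#' Recording duration in seconds
#' @param rec An [eeg_recording()].
#' @return Duration in seconds.
#' @export
duration_s <- function(rec) nrow(rec$samples) / rec$fs

n_channels <- function(rec) ncol(rec$samples)

#' Re-reference a referential recording to a bipolar montage
#'
#' Each output channel is the sample-wise difference anode - cathode, so the
#' shared reference potential cancels exactly.
#'
#' @param rec A referential [eeg_recording()].
#' @param pairs List of 2-element character vectors `c(anode, cathode)`,
#'   e.g. `list(c("F7","T7"), c("F8","T8"))`.
#' @return A bipolar [eeg_recording()] with labels `"<anode><cathode>"`.
#' @export
to_bipolar <- function(rec, pairs = list(c("F7", "T7"), c("F8", "T8"))) {
  assert_that(inherits(rec, "eeg_recording"), "rec must be an eeg_recording")
  assert_that(rec$montage == "referential",
              "to_bipolar requires a referential montage")
  out <- matrix(0, nrow(rec$samples), length(pairs))
  labs <- character(length(pairs))
  for (i in seq_along(pairs)) {
    p <- normalize_channel_label(pairs[[i]])
    for (el in p) {
      if (!el %in% rec$channel_labels) {
        stop_validation("electrode not present in recording: ", el)
      }
    }
    out[, i] <- rec$samples[, p[1]] - rec$samples[, p[2]]
    labs[i] <- paste0(p[1], p[2])
  }
  eeg_recording(out, rec$fs, labs, montage = "bipolar",
                start_time = rec$start_time, events = rec$events)
}

#' Acquisition front-end specification
#'
#' Describes one configuration of a differential EEG acquisition chain:
#' sampling rate, programmable-gain-amplifier gain, reference voltage and
#' converter width. The per-bit resolution follows as
#' `2 * vref / (gain * 2^bits)` volts (full differential input span over the
#' code space).
#'
#' @param fs Sampling rate (Hz).
#' @param pga_gain Amplifier gain (V/V).
#' @param vref Reference voltage (V). Defaults to 4.5 V, the reference of
#'   the targeted 24-bit front end.
#' @param bits Converter width in bits.
#' @return An object of class `acquisition_spec` with a `resolution_uV`
#'   field (microvolts per bit).
#' @examples
#' acquisition_spec(fs = 250, pga_gain = 24)$resolution_uV  # ~0.023 uV/bit
#' @export
acquisition_spec <- function(fs = 250, pga_gain = 24, vref = 4.5, bits = 24) {
  assert_that(fs > 0 && pga_gain > 0 && vref > 0 && bits > 0,
              "all acquisition parameters must be positive")
  res_v <- 2 * vref / (pga_gain * 2^bits)
  structure(list(fs = fs, pga_gain = pga_gain, vref = vref, bits = bits,
                 resolution_v = res_v, resolution_uV = res_v * 1e6),
            class = "acquisition_spec")
}

#' @export
print.acquisition_spec <- function(x, ...) {
  cat(sprintf("<acquisition_spec> fs=%g Hz, gain=%g V/V, vref=%g V, %d bits (%.4g uV/bit)\n",
              x$fs, x$pga_gain, x$vref, x$bits, x$resolution_uV))
  invisible(x)
}

#' Write a recording as CSV
#'
#' One column per channel, a header row of labels, and a leading `time`
#' column in seconds.
#'
#' @param rec An [eeg_recording()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_csv_recording <- function(rec, path) {
  utils::write.csv(as.data.frame(rec), path, row.names = FALSE)
  invisible(path)
}

#' Read a recording from CSV
#'
#' Expects the layout written by [write_csv_recording()]: first column time
#' in seconds, remaining columns one channel each. The sampling rate is
#' inferred from the median time step.
#'
#' @param path CSV path.
#' @param montage Montage kind to record.
#' @return An [eeg_recording()].
#' @export
read_csv_recording <- function(path, montage = "referential") {
  df <- utils::read.csv(path, check.names = FALSE)
  assert_that(ncol(df) >= 2, "CSV must have a time column plus >=1 channel")
  tm <- df[[1]]
  dt <- stats::median(diff(tm))
  assert_that(is.finite(dt) && dt > 0, "non-increasing time column")
  eeg_recording(as.matrix(df[, -1, drop = FALSE]), fs = 1 / dt,
                channel_labels = names(df)[-1], montage = montage,
                start_time = tm[1])
}
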