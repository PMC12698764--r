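# 16-bit EDF reader/writer (classic EDF, not EDF+). Annotations travel in
# separate plain-text summaries, mirroring how public seizure corpora ship
# them. Data records are 1 s long, so the writer requires an integer
# sampling rate and whole-second durations (trailing partial seconds are
# truncated with a warning).

EDF_HEADER_BYTES <- 256L

pad_field <- function(x, width) {
  x <- as.character(x)
  if (nchar(x) > width) x <- substr(x, 1, width)
  formatC(x, width = -width)
}

#' Write a recording to a 16-bit EDF file
#'
#' Each channel is scaled to its own symmetric physical range (in
#' microvolts) over the full 16-bit digital span, so the quantization step
#' is `range/65535` and a write/read round-trip is exact to within one
#' least-significant bit.
#'
#' @param rec An [eeg_recording()] with integer `fs` and whole-second
#'   duration.
#' @param path Output path.
#' @param patient,recording_id Free-text header fields.
#' @return `path`, invisibly.
#' @export
write_edf <- function(rec, path, patient = "X", recording_id = "eegedge") {
  assert_that(inherits(rec, "eeg_recording"), "rec must be an eeg_recording")
  fs <- rec$fs
  assert_that(abs(fs - round(fs)) < 1e-9, "EDF writer requires integer fs")
  fs <- as.integer(round(fs))
  n <- nrow(rec$samples)
  n_rec <- n %/% fs
  assert_that(n_rec >= 1, "recording shorter than one 1-s data record")
  if (n_rec * fs != n) {
    warning("truncating ", n - n_rec * fs, " samples (partial final EDF record)")
  }
  ns <- ncol(rec$samples)
  x_uv <- rec$samples[seq_len(n_rec * fs), , drop = FALSE] * 1e6

  phys_max <- apply(abs(x_uv), 2, max)
  phys_max[phys_max == 0] <- 1
  phys_max <- signif(phys_max * 1.0001, 7)  # headroom so max maps inside span
  dig_min <- -32768L; dig_max <- 32767L

  # montage tag kept in the reserved field; bipolar labels written with "-"
  labels <- rec$channel_labels
  if (rec$montage == "bipolar") {
    labels <- sub("^([A-Z]{1,2}[0-9Z]{1,2})([A-Z]{1,2}[0-9Z]{1,2})$",
                  "\\1-\\2", labels)
  }

  header <- paste0(
    pad_field("0", 8), pad_field(patient, 80), pad_field(recording_id, 80),
    pad_field("01.01.00", 8), pad_field("00.00.00", 8),
    pad_field(EDF_HEADER_BYTES * (1L + ns), 8),
    pad_field(rec$montage, 44),
    pad_field(n_rec, 8), pad_field(1, 8), pad_field(ns, 4))
  sig_header <- paste0(
    paste(vapply(labels, pad_field, "", width = 16), collapse = ""),
    paste(rep(pad_field("", 80), ns), collapse = ""),
    paste(rep(pad_field("uV", 8), ns), collapse = ""),
    paste(vapply(-phys_max, pad_field, "", width = 8), collapse = ""),
    paste(vapply(phys_max, pad_field, "", width = 8), collapse = ""),
    paste(rep(pad_field(dig_min, 8), ns), collapse = ""),
    paste(rep(pad_field(dig_max, 8), ns), collapse = ""),
    paste(rep(pad_field("", 80), ns), collapse = ""),
    paste(rep(pad_field(fs, 8), ns), collapse = ""),
    paste(rep(pad_field("", 32), ns), collapse = ""))

  scale <- (dig_max - dig_min) / (2 * phys_max)
  dig <- sweep(x_uv, 2, scale, `*`)
  dig <- round(dig + (dig_max + dig_min) / 2)
  dig <- pmin(pmax(dig, dig_min), dig_max)
  storage.mode(dig) <- "integer"

  con <- file(path, "wb")
  on.exit(close(con))
  writeChar(paste0(header, sig_header), con, eos = NULL)
  # data records: per record, all samples of signal 1, then signal 2, ...
  idx <- matrix(seq_len(n_rec * fs), nrow = fs)
  for (r in seq_len(n_rec)) {
    writeBin(as.vector(dig[idx[, r], ]), con, size = 2, endian = "little")
  }
  invisible(path)
}

#' Read a 16-bit EDF file
#'
#' Classic EDF with uniform per-channel sampling rates. Labels are
#' normalized ([normalize_channel_label()]); a file whose labels are
#' electrode pairs (e.g. `"F7-T7"`) is flagged as a bipolar montage.
#' Amplitudes are converted to volts from the header's physical dimension
#' (`uV`, `mV`, or `V`).
#'
#' @param path EDF file path.
#' @return An [eeg_recording()] (events empty; annotations are read
#'   separately with [read_annotation_summary()]).
#' @export
read_edf <- function(path) {
  assert_that(file.exists(path), "EDF file not found: ", path)
  sz <- file.info(path)$size
  if (is.na(sz) || sz < EDF_HEADER_BYTES) {
    stop_format("not a valid EDF file (", sz, " bytes, header needs 256): ", path)
  }
  con <- file(path, "rb")
  on.exit(close(con))
  hdr <- readChar(con, EDF_HEADER_BYTES, useBytes = TRUE)
  field <- function(from, len) trimws(substr(hdr, from, from + len - 1))
  n_rec <- suppressWarnings(as.integer(field(237, 8)))
  rec_dur <- suppressWarnings(as.numeric(field(245, 8)))
  ns <- suppressWarnings(as.integer(field(253, 4)))
  if (is.na(ns) || ns < 1) stop_format("malformed EDF header: number of signals")
  if (is.na(n_rec) || n_rec < 1) stop_format("malformed EDF header: number of data records")
  if (is.na(rec_dur) || rec_dur <= 0) stop_format("malformed EDF header: record duration")
  montage_tag <- field(193, 44)

  sig_hdr <- readChar(con, EDF_HEADER_BYTES * ns, useBytes = TRUE)
  # signal headers are concatenated field-by-field: label(16) transducer(80)
  # dim(8) pmin(8) pmax(8) dmin(8) dmax(8) prefilter(80) nsamp(8) reserved(32)
  off <- c(label = 0, transducer = 16, dim = 96, pmin = 104, pmax = 112,
           dmin = 120, dmax = 128, prefilter = 136, nsamp = 216)
  grab <- function(name, len) {
    start <- off[[name]] * ns
    vapply(seq_len(ns), function(i) {
      trimws(substr(sig_hdr, start + (i - 1) * len + 1, start + i * len))
    }, "")
  }
  raw_labels <- grab("label", 16)
  phys_dim <- grab("dim", 8)
  pmin <- as.numeric(grab("pmin", 8)); pmax <- as.numeric(grab("pmax", 8))
  dmin <- as.numeric(grab("dmin", 8)); dmax <- as.numeric(grab("dmax", 8))
  nsamp <- as.integer(grab("nsamp", 8))
  if (anyNA(c(pmin, pmax, dmin, dmax, nsamp))) {
    stop_format("malformed EDF signal header: non-numeric scaling fields")
  }
  if (length(unique(nsamp)) != 1) {
    stop_format("unsupported EDF layout: mixed per-signal sampling rates (",
                paste(unique(nsamp), collapse = ", "), " samples/record)")
  }
  fs <- nsamp[1] / rec_dur

  expected <- n_rec * sum(nsamp) * 2
  dat <- readBin(con, "integer", n = n_rec * sum(nsamp), size = 2,
                 endian = "little", signed = TRUE)
  if (length(dat) != n_rec * sum(nsamp)) {
    stop_format("EDF data truncated: expected ", expected, " bytes of samples")
  }
  dat <- array(dat, dim = c(nsamp[1], ns, n_rec))
  x <- matrix(0, nsamp[1] * n_rec, ns)
  for (i in seq_len(ns)) x[, i] <- as.vector(dat[, i, ])

  unit <- vapply(phys_dim, function(u) {
    switch(tolower(u), "uv" = 1e-6, "mv" = 1e-3, "v" = 1, 1e-6)
  }, 1.0)
  for (i in seq_len(ns)) {
    gain <- (pmax[i] - pmin[i]) / (dmax[i] - dmin[i])
    x[, i] <- ((x[, i] - dmin[i]) * gain + pmin[i]) * unit[i]
  }

  bipolar <- identical(montage_tag, "bipolar") ||
    all(grepl("^[A-Za-z]{1,2}[0-9Zz]{1,2}-[A-Za-z]{1,2}[0-9Zz]{1,2}$", raw_labels))
  eeg_recording(x, fs = fs, channel_labels = raw_labels,
                montage = if (bipolar) "bipolar" else "referential")
}
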