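#' Annotated event intervals
#'
#' An `event_list` is a data frame of half-open intervals `[onset, offset)`
#' in seconds from record start, with a character `label` per event.
#' Events are sorted by onset on construction and overlapping (or touching)
#' events sharing a label are merged, so downstream interval arithmetic can
#' assume a canonical form.
#'
#' @param onset,offset Numeric vectors of interval bounds in seconds;
#'   `onset < offset` element-wise.
#' @param label Character vector of event labels (recycled), default
#'   `"seizure"`.
#' @return An object of class `event_list` (a data frame with columns
#'   `onset`, `offset`, `label`).
#' @examples
#' event_list(c(10, 35), c(40, 60))  # overlapping seizures merge to 10-60
#' @export
event_list <- function(onset = numeric(), offset = numeric(), label = "seizure") {
  onset <- as.numeric(onset)
  offset <- as.numeric(offset)
  assert_that(length(onset) == length(offset),
              "onset and offset must have equal length")
  if (length(onset)) {
    bad <- which(!(onset < offset))
    if (length(bad)) {
      stop_validation("event offset must exceed onset (violated at event ",
                      bad[1], ": [", onset[bad[1]], ", ", offset[bad[1]], "))")
    }
  }
  label <- rep_len(as.character(label), length(onset))
  ev <- data.frame(onset = onset, offset = offset, label = label,
                   stringsAsFactors = FALSE)
  ev <- merge_events(ev)
  class(ev) <- c("event_list", "data.frame")
  ev
}

# Merge overlapping same-label intervals; result sorted by onset.
merge_events <- function(ev) {
  if (nrow(ev) <= 1) return(ev[order(ev$onset), , drop = FALSE])
  out <- lapply(split(ev, ev$label), function(g) {
    g <- g[order(g$onset, g$offset), , drop = FALSE]
    keep_on <- g$onset[1]
    keep_off <- g$offset[1]
    ons <- offs <- numeric(0)
    for (i in seq_len(nrow(g))[-1]) {
      if (g$onset[i] <= keep_off) {
        keep_off <- max(keep_off, g$offset[i])
      } else {
        ons <- c(ons, keep_on); offs <- c(offs, keep_off)
        keep_on <- g$onset[i]; keep_off <- g$offset[i]
      }
    }
    ons <- c(ons, keep_on); offs <- c(offs, keep_off)
    data.frame(onset = ons, offset = offs, label = g$label[1],
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, out)
  rownames(out) <- NULL
  out[order(out$onset), , drop = FALSE]
}

#' @export
print.event_list <- function(x, ...) {
  cat("<event_list> ", nrow(x), " event(s)\n", sep = "")
  if (nrow(x)) print.data.frame(x, row.names = FALSE)
  invisible(x)
}

n_events <- function(ev) if (is.null(ev)) 0L else nrow(ev)

# Shift all events by dt seconds (used when concatenating records on a
# subject timeline).
shift_events <- function(ev, dt) {
  if (!n_events(ev)) return(ev)
  ev$onset <- ev$onset + dt
  ev$offset <- ev$offset + dt
  ev
}

#' Read a plain-text seizure annotation summary
#'
#' Parses the CHB-MIT-style summary dialect: for each record a block with
#' `Number of Seizures in File: n` followed by
#' `Seizure [k] Start Time: s seconds` / `Seizure [k] End Time: s seconds`
#' lines. Only the start/end lines are interpreted; all times are seconds
#' from record start. Overlapping intervals are merged on construction.
#'
#' @param path Path to the summary text file.
#' @param label Label to give every parsed event.
#' @return An [event_list()].
#' @export
read_annotation_summary <- function(path, label = "seizure") {
  assert_that(file.exists(path), "annotation summary not found: ", path)
  lines <- readLines(path, warn = FALSE)
  starts <- ends <- numeric(0)
  start_lines <- integer(0)
  for (i in seq_along(lines)) {
    ln <- lines[i]
    if (grepl("Seizure.*Start Time", ln, ignore.case = TRUE)) {
      starts <- c(starts, parse_seconds(ln, i))
      start_lines <- c(start_lines, i)
    } else if (grepl("Seizure.*End Time", ln, ignore.case = TRUE)) {
      ends <- c(ends, parse_seconds(ln, i))
    }
  }
  if (length(starts) != length(ends)) {
    stop_format("unbalanced seizure start/end lines in ", path,
                " (", length(starts), " starts, ", length(ends), " ends)")
  }
  bad <- which(ends <= starts)
  if (length(bad)) {
    stop_validation("seizure end time not after start time at line ",
                    start_lines[bad[1]], " of ", path)
  }
  event_list(starts, ends, label = label)
}

parse_seconds <- function(line, lineno) {
  tail <- sub("^[^:]*:", "", line)
  m <- regmatches(tail, regexpr("[0-9]+(\\.[0-9]+)?", tail))
  if (!length(m)) stop_format("no numeric time on line ", lineno, ": ", line)
  as.numeric(m)
}

#' Write a plain-text seizure annotation summary
#'
#' Emits the same dialect [read_annotation_summary()] parses, enabling
#' round-trips between the detector's alarm output and the scorer.
#'
#' @param events An [event_list()].
#' @param path Output file path.
#' @param file_name Record file name written in the header line.
#' @param fs Sampling rate echoed in the header (Hz).
#' @return `path`, invisibly.
#' @export
write_annotation_summary <- function(events, path, file_name = "record.edf",
                                     fs = NULL) {
  lines <- character(0)
  if (!is.null(fs)) {
    lines <- c(lines, sprintf("Data Sampling Rate: %g Hz", fs), "")
  }
  lines <- c(lines,
             sprintf("File Name: %s", file_name),
             sprintf("Number of Seizures in File: %d", n_events(events)))
  if (n_events(events)) {
    for (k in seq_len(nrow(events))) {
      lines <- c(lines,
                 sprintf("Seizure %d Start Time: %g seconds", k, events$onset[k]),
                 sprintf("Seizure %d End Time: %g seconds", k, events$offset[k]))
    }
  }
  writeLines(lines, path)
  invisible(path)
}
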