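#' Spike train objects
#'
#' A `spike_train` holds the sorted spike times (seconds) of one sorted unit
#' over one recording, together with the recording duration. Spike sorting is
#' assumed to have happened upstream; this package consumes event times only.
#'
#' @param spike_times numeric vector of spike times in seconds, sorted
#'   non-decreasing, all within `[0, duration]`.
#' @param duration recording duration in seconds.
#' @param unit_id character identifier for the unit.
#' @return an object of class `spike_train` with fields `unit_id`,
#'   `spike_times` and `duration`.
#' @examples
#' st <- spike_train(c(0.1, 0.5, 2.2), duration = 10, unit_id = "u1")
#' length(st$spike_times)
#' @export
spike_train <- function(spike_times, duration, unit_id = "unit") {
  spike_times <- as.numeric(spike_times)
  stopifnot_scalar(duration, "duration", positive = TRUE)
  if (anyNA(spike_times)) stop("spike times must not contain NA", call. = FALSE)
  if (is.unsorted(spike_times)) {
    stop("spike times must be sorted non-decreasing", call. = FALSE)
  }
  if (length(spike_times) && (spike_times[1L] < 0 ||
                              spike_times[length(spike_times)] > duration)) {
    stop("spike times must lie within [0, duration]", call. = FALSE)
  }
  structure(
    list(unit_id = as.character(unit_id),
         spike_times = spike_times,
         duration = as.numeric(duration)),
    class = "spike_train"
  )
}

#' @export
print.spike_train <- function(x, ...) {
  cat(sprintf("<spike_train> unit '%s': %d spikes over %.3f s (mean rate %.2f Hz)\n",
              x$unit_id, length(x$spike_times), x$duration,
              length(x$spike_times) / x$duration))
  invisible(x)
}

#' Write spike trains to delimited text
#'
#' Writes one or more spike trains as tab-separated text with columns
#' `unit_id` and `spike_time_s`. Times are written with 9 fractional digits
#' so a write/read round trip is lossless to well below 1e-9 s. Recording
#' durations are preserved in `#` comment header lines.
#'
#' @param trains a `spike_train` or list of them.
#' @param path output file path.
#' @return `path`, invisibly.
#' @seealso [read_spike_trains()]
#' @export
write_spike_trains <- function(trains, path) {
  if (inherits(trains, "spike_train")) trains <- list(trains)
  con <- file(path, open = "wt")
  on.exit(close(con))
  for (tr in trains) {
    stopifnot(inherits(tr, "spike_train"))
    writeLines(sprintf("# unit %s duration_s %.9f", tr$unit_id, tr$duration), con)
  }
  writeLines("unit_id\tspike_time_s", con)
  for (tr in trains) {
    if (length(tr$spike_times)) {
      writeLines(sprintf("%s\t%.9f", tr$unit_id, tr$spike_times), con)
    }
  }
  invisible(path)
}

#' Read spike trains from delimited text
#'
#' Parses files produced by [write_spike_trains()] (or equivalent two-column
#' delimited text). Rows that fail to parse, negative times, times beyond the
#' stated duration, and unsorted times within a unit raise an error naming
#' the offending line. Units declared in the header but owning zero spikes
#' are returned with an empty spike vector.
#'
#' @param path input file path.
#' @param default_duration duration assigned to units with no header line;
#'   defaults to the last spike time of that unit.
#' @return list of `spike_train` objects.
#' @export
read_spike_trains <- function(path, default_duration = NULL) {
  lines <- readLines(path)
  durations <- list()
  header_units <- character()
  is_comment <- startsWith(lines, "#")
  for (ln in lines[is_comment]) {
    m <- regmatches(ln, regexec("^#\\s*unit\\s+(\\S+)\\s+duration_s\\s+(\\S+)", ln))[[1L]]
    if (length(m) == 3L) {
      durations[[m[2L]]] <- as.numeric(m[3L])
      header_units <- c(header_units, m[2L])
    }
  }
  body_idx <- which(!is_comment)
  # drop the column-name row if present
  if (length(body_idx) && grepl("^unit_id", lines[body_idx[1L]])) {
    body_idx <- body_idx[-1L]
  }
  ids <- character(length(body_idx))
  times <- numeric(length(body_idx))
  for (k in seq_along(body_idx)) {
    i <- body_idx[k]
    fields <- strsplit(lines[i], "[\t,;[:space:]]+")[[1L]]
    fields <- fields[nzchar(fields)]
    if (length(fields) != 2L) {
      stop(sprintf("line %d: expected 2 fields, found %d", i, length(fields)),
           call. = FALSE)
    }
    tm <- suppressWarnings(as.numeric(fields[2L]))
    if (is.na(tm)) {
      stop(sprintf("line %d: spike time '%s' is not numeric", i, fields[2L]),
           call. = FALSE)
    }
    if (tm < 0) {
      stop(sprintf("line %d: negative spike time %g", i, tm), call. = FALSE)
    }
    ids[k] <- fields[1L]
    times[k] <- tm
  }
  unit_order <- unique(c(header_units, ids))
  out <- vector("list", length(unit_order))
  names(out) <- unit_order
  for (u in unit_order) {
    tu <- times[ids == u]
    if (is.unsorted(tu)) {
      first_bad <- body_idx[ids == u][which(diff(tu) < 0)[1L] + 1L]
      stop(sprintf("line %d: spike times of unit '%s' are not sorted",
                   first_bad, u), call. = FALSE)
    }
    dur <- durations[[u]]
    if (is.null(dur)) {
      dur <- if (!is.null(default_duration)) default_duration
             else if (length(tu)) max(tu) else 1
    }
    out[[u]] <- spike_train(tu, duration = dur, unit_id = u)
  }
  out
}
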