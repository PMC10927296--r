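#' Stimulus protocols
#'
#' A `stimulus_protocol` describes the sequence of optogenetic stimulation
#' events of a recording. Each event is either a `single` 1-ms light pulse or
#' a `train` of five 1-ms pulses at 20 Hz (50-ms spacing); a train is stored
#' once, as its first-pulse onset, and expanded on demand by
#' [pulse_onsets()]. Typical designs deliver single pulses every 5 s and
#' trains every 10 s, with at least 40 repeats per cell.
#'
#' @param onset numeric vector of event onsets in seconds (first pulse for
#'   trains), sorted ascending.
#' @param kind character vector, `"single"` or `"train"`, recycled.
#' @param power_mW light power per event in mW, recycled. Powers above
#'   `max_power_mW` are rejected; `max_power_mW` itself marks the strongest
#'   power tested in an experiment and is metadata, not an algorithmic input.
#' @param pulse_width light pulse width in seconds (default 1 ms).
#' @param train_pulse_count pulses per train event (default 5).
#' @param train_interval within-train pulse spacing in seconds (default
#'   0.05, i.e. 20 Hz).
#' @param max_power_mW strongest power tested (default 8).
#' @return an object of class `stimulus_protocol` with an `events` data frame
#'   (`onset`, `kind`, `power_mW`) plus the protocol constants.
#' @examples
#' p <- stimulus_protocol(onset = c(5, 10), kind = "train", power_mW = 1)
#' pulse_onsets(p)
#' @export
stimulus_protocol <- function(onset, kind = "single", power_mW = 1,
                              pulse_width = 0.001, train_pulse_count = 5L,
                              train_interval = 0.05, max_power_mW = 8) {
  onset <- as.numeric(onset)
  if (is.unsorted(onset)) stop("event onsets must be sorted", call. = FALSE)
  n <- length(onset)
  kind <- rep_len(as.character(kind), n)
  power_mW <- rep_len(as.numeric(power_mW), n)
  bad <- setdiff(unique(kind), c("single", "train"))
  if (length(bad)) {
    stop(sprintf("unknown event kind: %s", paste(sQuote(bad), collapse = ", ")),
         call. = FALSE)
  }
  if (any(power_mW < 0)) stop("power_mW must be >= 0", call. = FALSE)
  if (any(power_mW > max_power_mW)) {
    stop(sprintf("power_mW exceeds the maximum tested power (%g mW)", max_power_mW),
         call. = FALSE)
  }
  structure(
    list(events = data.frame(onset = onset, kind = kind, power_mW = power_mW,
                             stringsAsFactors = FALSE),
         pulse_width = pulse_width,
         train_pulse_count = as.integer(train_pulse_count),
         train_interval = train_interval,
         max_power_mW = max_power_mW),
    class = "stimulus_protocol"
  )
}

#' @export
print.stimulus_protocol <- function(x, ...) {
  tab <- table(x$events$kind)
  cat(sprintf("<stimulus_protocol> %d events (%s); powers %s mW\n",
              nrow(x$events),
              paste(sprintf("%s %s", tab, names(tab)), collapse = ", "),
              paste(sort(unique(x$events$power_mW)), collapse = "/")))
  invisible(x)
}

#' Expand protocol events into individual pulse onsets
#'
#' Single events contribute one pulse; train events are expanded into
#' `train_pulse_count` pulses spaced `train_interval` apart.
#'
#' @param protocol a [stimulus_protocol()].
#' @return data frame with one row per light pulse: `onset`, `event_index`,
#'   `pulse_index` (position within the train, 1 for singles), `kind`,
#'   `power_mW`.
#' @export
pulse_onsets <- function(protocol) {
  stopifnot(inherits(protocol, "stimulus_protocol"))
  ev <- protocol$events
  out <- vector("list", nrow(ev))
  for (i in seq_len(nrow(ev))) {
    np <- if (ev$kind[i] == "train") protocol$train_pulse_count else 1L
    out[[i]] <- data.frame(
      onset = ev$onset[i] + (seq_len(np) - 1L) * protocol$train_interval,
      event_index = i,
      pulse_index = seq_len(np),
      kind = ev$kind[i],
      power_mW = ev$power_mW[i],
      stringsAsFactors = FALSE
    )
  }
  do.call(rbind, out)
}

#' Convenience constructors for the standard stimulation designs
#'
#' `single_pulse_protocol()` builds the single-pulse design (events every
#' `spacing` = 5 s); `train_protocol()` builds the five-pulse 20-Hz train
#' design (trains every `spacing` = 10 s). The first event is placed at
#' `start` seconds so that a full pre-stimulus baseline window is available.
#'
#' @param n_events number of stimulation events.
#' @param spacing event spacing in seconds.
#' @param power_mW light power in mW.
#' @param start onset of the first event in seconds.
#' @param ... passed on to [stimulus_protocol()].
#' @return a [stimulus_protocol()].
#' @export
single_pulse_protocol <- function(n_events = 40L, spacing = 5, power_mW = 1,
                                  start = 5, ...) {
  stimulus_protocol(onset = start + (seq_len(n_events) - 1L) * spacing,
                    kind = "single", power_mW = power_mW, ...)
}

#' @rdname single_pulse_protocol
#' @export
train_protocol <- function(n_events = 40L, spacing = 10, power_mW = 1,
                           start = 5, ...) {
  stimulus_protocol(onset = start + (seq_len(n_events) - 1L) * spacing,
                    kind = "train", power_mW = power_mW, ...)
}

#' Read / write stimulus protocols as JSON
#'
#' Protocols are stored as a JSON object holding the protocol constants and
#' the event table. Train events are stored once (first-pulse onset) and
#' expanded on load by [pulse_onsets()], keeping the files human-auditable.
#'
#' @param protocol a [stimulus_protocol()].
#' @param path file path.
#' @return `read_protocol()` returns a [stimulus_protocol()];
#'   `write_protocol()` returns `path` invisibly.
#' @export
write_protocol <- function(protocol, path) {
  stopifnot(inherits(protocol, "stimulus_protocol"))
  obj <- list(
    pulse_width_s = protocol$pulse_width,
    train_pulse_count = protocol$train_pulse_count,
    train_interval_s = protocol$train_interval,
    max_power_mW = protocol$max_power_mW,
    events = lapply(seq_len(nrow(protocol$events)), function(i) {
      list(onset_s = protocol$events$onset[i],
           kind = protocol$events$kind[i],
           power_mW = protocol$events$power_mW[i])
    })
  )
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_protocol
#' @export
read_protocol <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  ev <- obj$events
  if (is.null(ev) || !nrow(as.data.frame(ev))) {
    stop("protocol file contains no events", call. = FALSE)
  }
  ev <- as.data.frame(ev)
  stimulus_protocol(
    onset = ev$onset_s, kind = ev$kind, power_mW = ev$power_mW,
    pulse_width = obj$pulse_width_s %||% 0.001,
    train_pulse_count = obj$train_pulse_count %||% 5L,
    train_interval = obj$train_interval_s %||% 0.05,
    max_power_mW = obj$max_power_mW %||% 8
  )
}

`%||%` <- function(a, b) if (is.null(a)) b else a
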