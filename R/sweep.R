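#' Voltage-clamp sweep objects
#'
#' A `vc_sweep` is a whole-cell voltage-clamp current trace (pA) sampled at a
#' fixed rate, with the light-pulse onsets used during the sweep. The holding
#' potential is carried as metadata (recordings here are clamped at -60 mV
#' unless stated otherwise); inward synaptic currents appear as negative
#' deflections of the trace.
#'
#' @param samples numeric vector, membrane current in pA.
#' @param sampling_rate sampling rate in Hz (default 10000: data in this
#'   preparation are acquired at 10 kHz).
#' @param pulse_times light pulse onsets in seconds, all within the trace.
#' @param holding_potential holding potential in mV (metadata, default -60).
#' @return object of class `vc_sweep`.
#' @export
vc_sweep <- function(samples, sampling_rate = 10000, pulse_times = numeric(),
                     holding_potential = -60) {
  stopifnot_scalar(sampling_rate, "sampling_rate", positive = TRUE)
  samples <- as.numeric(samples)
  pulse_times <- as.numeric(pulse_times)
  span <- length(samples) / sampling_rate
  if (length(pulse_times) && (min(pulse_times) < 0 || max(pulse_times) > span)) {
    stop("pulse_times must lie within the trace span", call. = FALSE)
  }
  if (is.unsorted(pulse_times)) stop("pulse_times must be sorted", call. = FALSE)
  structure(
    list(samples = samples, sampling_rate = sampling_rate,
         pulse_times = pulse_times, holding_potential = holding_potential),
    class = "vc_sweep"
  )
}

#' @export
print.vc_sweep <- function(x, ...) {
  cat(sprintf("<vc_sweep> %d samples @ %g kHz (%.3f s), %d pulses, holding %g mV\n",
              length(x$samples), x$sampling_rate / 1000,
              length(x$samples) / x$sampling_rate,
              length(x$pulse_times), x$holding_potential))
  invisible(x)
}

# Sample times of a sweep (seconds, first sample at t = 0).
sweep_times <- function(sweep) {
  (seq_along(sweep$samples) - 1L) / sweep$sampling_rate
}

#' Write / read voltage-clamp sweeps
#'
#' Each sweep is written as two-column tab-separated text (`time_s`,
#' `current_pA`) next to a single JSON sidecar holding the shared metadata
#' (`sampling_rate`, `pulse_times`, `holding_potential`) and the list of
#' sweep files. `read_sweeps()` takes the sidecar path.
#'
#' @param sweeps a `vc_sweep` or list of them (all sharing metadata).
#' @param dir output directory (created if needed).
#' @param prefix file-name prefix for the sweep files and sidecar.
#' @return `write_sweeps()` returns the sidecar path invisibly;
#'   `read_sweeps()` returns a list of `vc_sweep` objects.
#' @export
write_sweeps <- function(sweeps, dir, prefix = "sweep") {
  if (inherits(sweeps, "vc_sweep")) sweeps <- list(sweeps)
  stopifnot(length(sweeps) > 0L, all(vapply(sweeps, inherits, TRUE, "vc_sweep")))
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  files <- sprintf("%s_%03d.tsv", prefix, seq_along(sweeps))
  for (i in seq_along(sweeps)) {
    sw <- sweeps[[i]]
    df <- data.frame(time_s = sprintf("%.9f", sweep_times(sw)),
                     current_pA = sprintf("%.6f", sw$samples))
    utils::write.table(df, file.path(dir, files[i]), sep = "\t",
                       quote = FALSE, row.names = FALSE)
  }
  sidecar <- file.path(dir, paste0(prefix, ".json"))
  jsonlite::write_json(
    list(sampling_rate = sweeps[[1L]]$sampling_rate,
         pulse_times = sweeps[[1L]]$pulse_times,
         holding_potential = sweeps[[1L]]$holding_potential,
         files = files),
    sidecar, auto_unbox = TRUE, digits = NA
  )
  invisible(sidecar)
}

#' @rdname write_sweeps
#' @param sidecar path to the JSON sidecar written by `write_sweeps()`.
#' @export
read_sweeps <- function(sidecar) {
  meta <- jsonlite::read_json(sidecar, simplifyVector = TRUE)
  rate <- meta$sampling_rate %||% 10000
  dir <- dirname(sidecar)
  lapply(meta$files, function(f) {
    df <- utils::read.table(file.path(dir, f), header = TRUE, sep = "\t")
    if (!all(c("time_s", "current_pA") %in% names(df))) {
      stop(sprintf("sweep file '%s' lacks time_s/current_pA columns", f),
           call. = FALSE)
    }
    vc_sweep(df$current_pA, sampling_rate = rate,
             pulse_times = as.numeric(meta$pulse_times %||% numeric()),
             holding_potential = meta$holding_potential %||% -60)
  })
}
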