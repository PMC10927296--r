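#' Measure an evoked EPSC amplitude
#'
#' Measures the peak amplitude of a light-evoked EPSC against a local
#' pre-pulse baseline: `local_baseline` is the mean current over
#' `[pulse_time - baseline_window, pulse_time)` and the amplitude is the
#' largest inward (negative-going) deflection from that baseline within
#' `(pulse_time, pulse_time + search_window]`, reported as a positive
#' magnitude in pA. The peak is the extremal sample; no curve fitting.
#'
#' Local baselining per pulse, rather than one global baseline, removes the
#' residual decay of a preceding EPSC within a 20-Hz train and tracks the
#' slow subthreshold membrane oscillation these cells exhibit, provided the
#' oscillation period is long compared with `baseline_window`.
#'
#' If `clip_limit` is given, any sample in the baseline or search window at
#' or beyond that magnitude marks the measurement as saturated (flag
#' `"clipped"`).
#'
#' @param sweep a [vc_sweep()].
#' @param pulse_time pulse onset, s; `pulse_time + search_window` must lie
#'   within the sweep.
#' @param search_window post-pulse search extent, s (default 0.020).
#' @param baseline_window pre-pulse baseline span, s (default 0.005).
#' @param clip_limit optional absolute current (pA) marking amplifier
#'   saturation.
#' @return list with `amplitude` (pA, positive magnitude),
#'   `local_baseline` (pA), `peak_time` (s) and `flags`.
#' @export
measure_epsc <- function(sweep, pulse_time, search_window = 0.020,
                         baseline_window = 0.005, clip_limit = NULL) {
  stopifnot(inherits(sweep, "vc_sweep"))
  stopifnot_scalar(pulse_time, "pulse_time", nonneg = TRUE)
  fs <- sweep$sampling_rate
  n <- length(sweep$samples)
  if ((pulse_time + search_window) * fs > n) {
    stop("pulse_time + search_window extends beyond the sweep", call. = FALSE)
  }
  # sample i covers time (i-1)/fs; indices in [t0, t1)
  idx_range <- function(t0, t1) {
    i0 <- max(1L, floor(t0 * fs + 1e-9) + 1L)
    i1 <- min(n, ceiling(t1 * fs - 1e-9))
    if (i1 < i0) integer() else i0:i1
  }
  ib <- idx_range(pulse_time - baseline_window, pulse_time)
  if (!length(ib)) stop("no samples in the baseline window", call. = FALSE)
  local_baseline <- mean(sweep$samples[ib])
  is_ <- idx_range(pulse_time + 1 / fs, pulse_time + search_window + 1 / fs)
  seg <- sweep$samples[is_]
  imin <- which.min(seg)
  amplitude <- local_baseline - seg[imin]
  flags <- character()
  if (!is.null(clip_limit) &&
      any(abs(c(sweep$samples[ib], seg)) >= clip_limit)) {
    flags <- "clipped"
  }
  list(amplitude = amplitude, local_baseline = local_baseline,
       peak_time = (is_[imin] - 1L) / fs, flags = flags)
}

#' EPSC train-depression profile
#'
#' Measures the per-pulse EPSC amplitudes of a five-pulse 20-Hz train,
#' normalizes them to the first pulse and derives depression percentages,
#' exactly as [train_profile()] does for spiking responses.
#'
#' By default the sweeps are averaged pointwise first and the amplitudes
#' measured on the average trace — the conventional treatment of repeated
#' voltage-clamp responses, which suppresses noise before the (noise-biased)
#' peak search. `method = "per-sweep"` instead measures every sweep and
#' averages the amplitudes.
#'
#' Each pulse is measured against its own local pre-pulse baseline, which
#' removes the residual decay of the previous EPSC. If the first-pulse
#' amplitude is not positive the normalization is undefined and the result
#' flagged `"nonpositive-first-pulse"`.
#'
#' @param sweeps a [vc_sweep()] or list of them (same sampling rate and
#'   length).
#' @param pulse_times pulse onsets, s; default taken from the first sweep's
#'   metadata. The standard protocol is five pulses at 50-ms spacing.
#' @param method `"average-trace"` (default) or `"per-sweep"`.
#' @param ... passed to [measure_epsc()] (`search_window`,
#'   `baseline_window`, `clip_limit`).
#' @return object of class `epsc_measurement`: `per_pulse_amplitude` (pA),
#'   `local_baseline` (pA per pulse), `normalized` (first = 1),
#'   `depression_1_to_2`, `depression_1_to_last` (percent), `n_sweeps`,
#'   `flags`.
#' @export
epsc_train_profile <- function(sweeps, pulse_times = NULL,
                               method = c("average-trace", "per-sweep"),
                               ...) {
  if (inherits(sweeps, "vc_sweep")) sweeps <- list(sweeps)
  stopifnot(length(sweeps) >= 1L,
            all(vapply(sweeps, inherits, TRUE, "vc_sweep")))
  method <- match.arg(method)
  if (is.null(pulse_times)) pulse_times <- sweeps[[1L]]$pulse_times
  pulse_times <- as.numeric(pulse_times)
  if (!length(pulse_times)) stop("pulse_times must be non-empty", call. = FALSE)
  np <- length(pulse_times)
  flags <- character()
  if (method == "average-trace") {
    len <- vapply(sweeps, function(s) length(s$samples), integer(1))
    if (length(unique(len)) != 1L) {
      stop("sweeps must have equal length to be averaged", call. = FALSE)
    }
    avg <- vc_sweep(rowMeans(do.call(cbind, lapply(sweeps, `[[`, "samples"))),
                    sampling_rate = sweeps[[1L]]$sampling_rate,
                    pulse_times = pulse_times,
                    holding_potential = sweeps[[1L]]$holding_potential)
    meas <- lapply(pulse_times, function(p) measure_epsc(avg, p, ...))
    amp <- vapply(meas, `[[`, numeric(1), "amplitude")
    base <- vapply(meas, `[[`, numeric(1), "local_baseline")
    flags <- unique(unlist(lapply(meas, `[[`, "flags")))
  } else {
    per_sweep <- vapply(sweeps, function(s) {
      vapply(pulse_times, function(p) {
        m <- measure_epsc(s, p, ...)
        if (length(m$flags)) flags <<- unique(c(flags, m$flags))
        m$amplitude
      }, numeric(1))
    }, numeric(np))
    per_sweep <- matrix(per_sweep, nrow = np)
    amp <- rowMeans(per_sweep)
    base <- vapply(pulse_times, function(p) {
      mean(vapply(sweeps, function(s)
        measure_epsc(s, p, ...)$local_baseline, numeric(1)))
    }, numeric(1))
  }
  if (amp[1L] <= 0) {
    flags <- c(flags, "nonpositive-first-pulse")
    normalized <- rep(NA_real_, np)
  } else {
    normalized <- amp / amp[1L]
  }
  structure(
    list(per_pulse_amplitude = amp,
         local_baseline = base,
         normalized = normalized,
         depression_1_to_2 = if (np >= 2L) (1 - normalized[2L]) * 100 else NA_real_,
         depression_1_to_last = (1 - normalized[np]) * 100,
         n_sweeps = length(sweeps),
         flags = flags),
    class = "epsc_measurement"
  )
}

#' @export
print.epsc_measurement <- function(x, ...) {
  cat(sprintf("<epsc_measurement> %d sweep(s); amplitudes (pA): %s\n",
              x$n_sweeps,
              paste(sprintf("%.1f", x$per_pulse_amplitude), collapse = ", ")))
  if (!anyNA(x$normalized)) {
    cat(sprintf("  normalized %s; depression 1->2 %.1f%%, 1->last %.1f%%\n",
                paste(sprintf("%.2f", x$normalized), collapse = ", "),
                x$depression_1_to_2, x$depression_1_to_last))
  }
  invisible(x)
}
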