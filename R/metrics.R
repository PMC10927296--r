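#' The extra-spikes statistic
#'
#' Counts the spikes that occur within `window` seconds after each stimulus
#' onset (half-open `[onset, onset + window)`), averages over trials, and
#' subtracts the count expected had the firing rate stayed at its baseline:
#' `mean count per trial - baseline_mean_rate * window`. The result is the
#' mean number of evoked (extra) spikes per stimulus; it is negative when
#' the stimulus suppresses firing and has expectation 0 for a homogeneous
#' train.
#'
#' @param train a [spike_train()].
#' @param onsets stimulus onsets, s (non-empty).
#' @param baseline_mean_rate baseline firing rate in Hz (>= 0), typically
#'   from [baseline_rate_before()] or [baseline_stats()].
#' @param window post-stimulus counting window, s (default 0.030: spikes
#'   within 30 ms of onset).
#' @return mean extra spikes per trial (numeric scalar).
#' @export
extra_spikes <- function(train, onsets, baseline_mean_rate, window = 0.030) {
  stopifnot(inherits(train, "spike_train"))
  onsets <- as.numeric(onsets)
  if (!length(onsets)) stop("onsets must be non-empty", call. = FALSE)
  stopifnot_scalar(window, "window", positive = TRUE)
  stopifnot_scalar(baseline_mean_rate, "baseline_mean_rate", nonneg = TRUE)
  counts <- count_in_windows(train$spike_times, onsets, onsets + window)
  mean(counts) - baseline_mean_rate * window
}

#' Baseline firing rate before a block of events
#'
#' Mean firing rate over the `span` seconds preceding each onset, pooled
#' across onsets: total spikes in the pre-windows divided by the total
#' baseline time. This is the baseline used for extra-spike subtraction,
#' recomputed per event block (for trains, the window precedes the first
#' pulse).
#'
#' @inheritParams extra_spikes
#' @param span pre-event span, s (default 3).
#' @return baseline rate in Hz.
#' @export
baseline_rate_before <- function(train, onsets, span = 3) {
  stopifnot(inherits(train, "spike_train"))
  onsets <- as.numeric(onsets)
  if (!length(onsets)) stop("onsets must be non-empty", call. = FALSE)
  stopifnot_scalar(span, "span", positive = TRUE)
  counts <- count_in_windows(train$spike_times, onsets - span, onsets)
  sum(counts) / (span * length(onsets))
}

#' Train-following response profile
#'
#' Computes the extra-spikes statistic separately for each pulse position of
#' a five-pulse 20-Hz train, normalizes each pulse's response to the first
#' pulse's, and derives depression percentages
#' (`depression_1_to_k = (1 - normalized[k]) * 100`). The per-pulse counting
#' window never overlaps the next pulse: it is capped at the within-train
#' pulse interval (with the standard 30-ms window and 50-ms spacing the full
#' window is used).
#'
#' If the first-pulse response is not positive the normalization is
#' undefined; the profile is returned with `normalized` and depressions set
#' to `NA` and flag `"nonpositive-first-pulse"`.
#'
#' @param train a [spike_train()].
#' @param protocol a [stimulus_protocol()] containing train events, or a
#'   numeric vector of first-pulse onsets (then `n_pulses`/`pulse_interval`
#'   apply).
#' @param baseline_mean_rate baseline rate, Hz; when `NULL`, computed with
#'   [baseline_rate_before()] from the 3 s preceding each first pulse.
#' @param window per-pulse counting window, s.
#' @param n_pulses,pulse_interval train geometry used when `protocol` is a
#'   plain onset vector.
#' @return object of class `train_response_profile`: `per_pulse_extra_spikes`
#'   (length 5), `normalized` (first exactly 1), `depression_1_to_2`,
#'   `depression_1_to_last` (percent), `baseline_mean_rate`, `n_trains`,
#'   `flags`.
#' @export
train_profile <- function(train, protocol, baseline_mean_rate = NULL,
                          window = 0.030, n_pulses = 5L,
                          pulse_interval = 0.05) {
  stopifnot(inherits(train, "spike_train"))
  if (inherits(protocol, "stimulus_protocol")) {
    ev <- protocol$events
    first_onsets <- ev$onset[ev$kind == "train"]
    if (!length(first_onsets)) {
      stop("protocol contains no train events", call. = FALSE)
    }
    n_pulses <- protocol$train_pulse_count
    pulse_interval <- protocol$train_interval
  } else {
    first_onsets <- as.numeric(protocol)
  }
  window <- min(window, pulse_interval)
  if (is.null(baseline_mean_rate)) {
    baseline_mean_rate <- baseline_rate_before(train, first_onsets)
  }
  per_pulse <- vapply(seq_len(n_pulses), function(k) {
    extra_spikes(train, first_onsets + (k - 1L) * pulse_interval,
                 baseline_mean_rate, window = window)
  }, numeric(1))
  flags <- character()
  if (per_pulse[1L] <= 0) {
    flags <- "nonpositive-first-pulse"
    normalized <- rep(NA_real_, n_pulses)
  } else {
    normalized <- per_pulse / per_pulse[1L]
  }
  structure(
    list(per_pulse_extra_spikes = per_pulse,
         normalized = normalized,
         depression_1_to_2 = (1 - normalized[2L]) * 100,
         depression_1_to_last = (1 - normalized[n_pulses]) * 100,
         baseline_mean_rate = baseline_mean_rate,
         n_trains = length(first_onsets),
         flags = flags),
    class = "train_response_profile"
  )
}

#' @export
print.train_response_profile <- function(x, ...) {
  cat(sprintf("<train_response_profile> %d trains; extra spikes %s\n",
              x$n_trains,
              paste(sprintf("%.2f", x$per_pulse_extra_spikes), collapse = ", ")))
  if (!anyNA(x$normalized)) {
    cat(sprintf("  normalized %s; depression 1->2 %.1f%%, 1->last %.1f%%\n",
                paste(sprintf("%.2f", x$normalized), collapse = ", "),
                x$depression_1_to_2, x$depression_1_to_last))
  } else {
    cat(sprintf("  normalization undefined [%s]\n", paste(x$flags, collapse = ", ")))
  }
  invisible(x)
}

#' Graded-intensity response curve
#'
#' Computes the extra-spikes statistic per light power across event groups
#' of increasing intensity and normalizes the curve to the 1-mW response:
#' measured directly when 1 mW was tested, linearly interpolated between the
#' bracketing powers otherwise; if all powers lie on one side of 1 mW the
#' nearest power is used and the result flagged `"nearest-power-reference"`.
#'
#' @param train a [spike_train()].
#' @param protocol a [stimulus_protocol()] whose single-pulse events span at
#'   least three distinct powers.
#' @param baseline_mean_rate baseline rate, Hz; `NULL` to recompute per
#'   power group from the 3 s preceding each event.
#' @param window counting window, s.
#' @param reference_mW normalization power (default 1).
#' @return object of class `graded_response`: `powers_mW` (strictly
#'   increasing), `extra_spikes`, `normalized_to_1mW`, `reference_response`,
#'   `flags`.
#' @export
graded_response <- function(train, protocol, baseline_mean_rate = NULL,
                            window = 0.030, reference_mW = 1) {
  stopifnot(inherits(train, "spike_train"),
            inherits(protocol, "stimulus_protocol"))
  ev <- protocol$events[protocol$events$kind == "single", ]
  powers <- sort(unique(ev$power_mW))
  if (length(powers) < 3L) {
    stop("graded analysis requires at least three distinct powers", call. = FALSE)
  }
  es <- vapply(powers, function(p) {
    on <- ev$onset[ev$power_mW == p]
    b <- if (is.null(baseline_mean_rate)) baseline_rate_before(train, on)
         else baseline_mean_rate
    extra_spikes(train, on, b, window = window)
  }, numeric(1))
  flags <- character()
  if (any(abs(powers - reference_mW) < 1e-12)) {
    ref <- es[which.min(abs(powers - reference_mW))]
  } else if (min(powers) < reference_mW && max(powers) > reference_mW) {
    ref <- stats::approx(powers, es, xout = reference_mW)$y
  } else {
    ref <- es[which.min(abs(powers - reference_mW))]
    flags <- "nearest-power-reference"
  }
  structure(
    list(powers_mW = powers, extra_spikes = es,
         normalized_to_1mW = es / ref, reference_response = ref,
         flags = flags),
    class = "graded_response"
  )
}

#' @export
print.graded_response <- function(x, ...) {
  cat("<graded_response>\n")
  print(data.frame(power_mW = x$powers_mW, extra_spikes = x$extra_spikes,
                   normalized = x$normalized_to_1mW))
  invisible(x)
}
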