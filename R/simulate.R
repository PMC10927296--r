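#' Configuration of a simulated unit
#'
#' Parameters of the generative model for one simulated single unit. Spikes
#' are drawn from an inhomogeneous Poisson process: a constant spontaneous
#' (baseline) rate, plus, per light pulse, a transient excitatory rate bump
#' and/or a multiplicative suppression window:
#'
#' * Excitation: each pulse contributes an expected
#'   `evoked_extra_spikes * depression_factors[k] * gain(power)` evoked
#'   spikes (pulse position `k` within a train). The evoked-rate kernel is
#'   anchored at `evoked_latency` after pulse onset with a causal half-normal
#'   jitter tail of scale `latency_jitter_sd`, so the onset of the evoked
#'   rate — the quantity a threshold-crossing latency estimator measures —
#'   equals `evoked_latency` exactly, making latency-recovery tests
#'   self-calibrating.
#' * Inhibition: over `[inhibition_onset, inhibition_onset +
#'   inhibition_duration)` after each pulse, the baseline rate is multiplied
#'   by `1 - inhibition_depth`.
#'
#' Which effects are active is set by `response_class` (`"Ex"`, `"Ex+In"`,
#' `"In"`, `"NR"`); inactive effects are ignored regardless of their
#' parameter values.
#'
#' @param baseline_rate spontaneous firing rate, events/s (>= 0). Spontaneous
#'   rates of precerebellar units are not pinned down by published summaries;
#'   the 10-Hz default is an assumption in the realistic 5-30 Hz range.
#' @param response_class one of `"Ex"`, `"Ex+In"`, `"In"`, `"NR"`.
#' @param evoked_latency onset of the evoked excitatory rate, s after pulse.
#' @param latency_jitter_sd scale of the half-normal evoked-spike-time
#'   jitter, s.
#' @param evoked_extra_spikes expected evoked spikes per pulse at unit gain
#'   (dimensionless, >= 0).
#' @param inhibition_onset suppression onset, s after pulse.
#' @param inhibition_duration suppression duration, s (> 0).
#' @param inhibition_depth fraction of the baseline rate suppressed, in
#'   `[0, 1]`.
#' @param depression_factors five multipliers in `(0, 1]` applied to the
#'   evoked area of pulses 1..5 of a train; first must be 1.
#' @param power_gain `NULL` for unit gain at any power, or a list
#'   `list(reference_mW=, exponent=)`: the evoked area is scaled by
#'   `(power / reference_mW) ^ exponent` (exponent 1 = response proportional
#'   to light power).
#' @param seed integer seed for this unit's private RNG stream, or `NULL` to
#'   draw from the current RNG state.
#' @return object of class `sim_unit_config`.
#' @export
sim_unit_config <- function(baseline_rate = 10,
                            response_class = c("Ex", "Ex+In", "In", "NR"),
                            evoked_latency = 0.0024,
                            latency_jitter_sd = 0.0003,
                            evoked_extra_spikes = 1,
                            inhibition_onset = 0.003,
                            inhibition_duration = 0.030,
                            inhibition_depth = 0.9,
                            depression_factors = rep(1, 5),
                            power_gain = NULL,
                            seed = NULL) {
  response_class <- match.arg(response_class)
  stopifnot_scalar(baseline_rate, "baseline_rate", nonneg = TRUE)
  stopifnot_scalar(evoked_extra_spikes, "evoked_extra_spikes", nonneg = TRUE)
  stopifnot_scalar(evoked_latency, "evoked_latency", nonneg = TRUE)
  stopifnot_scalar(latency_jitter_sd, "latency_jitter_sd", nonneg = TRUE)
  stopifnot_scalar(inhibition_duration, "inhibition_duration", positive = TRUE)
  if (inhibition_depth < 0 || inhibition_depth > 1) {
    stop("inhibition_depth must lie in [0, 1]", call. = FALSE)
  }
  if (length(depression_factors) < 1L || depression_factors[1L] != 1) {
    stop("depression_factors[1] must be 1", call. = FALSE)
  }
  if (any(depression_factors <= 0) || any(depression_factors > 1)) {
    stop("depression_factors must lie in (0, 1]", call. = FALSE)
  }
  structure(
    list(baseline_rate = baseline_rate, response_class = response_class,
         evoked_latency = evoked_latency,
         latency_jitter_sd = latency_jitter_sd,
         evoked_extra_spikes = evoked_extra_spikes,
         inhibition_onset = inhibition_onset,
         inhibition_duration = inhibition_duration,
         inhibition_depth = inhibition_depth,
         depression_factors = as.numeric(depression_factors),
         power_gain = power_gain,
         seed = if (is.null(seed)) NULL else as.integer(seed)),
    class = "sim_unit_config"
  )
}

power_gain_value <- function(cfg, power_mW) {
  if (is.null(cfg$power_gain)) return(rep(1, length(power_mW)))
  ref <- cfg$power_gain$reference_mW %||% 1
  expo <- cfg$power_gain$exponent %||% 1
  (power_mW / ref)^expo
}

# TRUE if the class includes an excitatory / inhibitory component.
class_has_ex <- function(cls) cls %in% c("Ex", "Ex+In")
class_has_in <- function(cls) cls %in% c("In", "Ex+In")

#' Simulate a spike train under a stimulus protocol
#'
#' Draws one unit's spikes from the inhomogeneous Poisson model described in
#' [sim_unit_config()]: a homogeneous baseline process, thinned inside each
#' pulse's suppression window with probability `inhibition_depth`, plus
#' Poisson-distributed evoked spikes per pulse at the configured latency and
#' jitter. Thinning a Poisson process and superposing independent Poisson
#' processes both yield Poisson processes, so the realized train is an exact
#' draw from the target rate function (see [unit_rate_function()]); no rate
#' clipping is ever needed because suppression is multiplicative with depth
#' at most 1. An empty protocol yields a baseline-only train.
#'
#' @param cfg a [sim_unit_config()].
#' @param protocol a [stimulus_protocol()]; its events must lie within
#'   `duration`.
#' @param duration recording duration, s; default extends 5 s past the last
#'   event.
#' @param unit_id identifier for the returned train.
#' @return a [spike_train()].
#' @export
simulate_spike_train <- function(cfg, protocol, duration = NULL,
                                 unit_id = "sim") {
  stopifnot(inherits(cfg, "sim_unit_config"),
            inherits(protocol, "stimulus_protocol"))
  pulses <- if (nrow(protocol$events)) pulse_onsets(protocol) else NULL
  if (is.null(duration)) {
    duration <- if (is.null(pulses)) 10 else max(pulses$onset) + 5
  }
  if (!is.null(pulses) && max(pulses$onset) > duration) {
    stop("protocol events must lie within the recording duration", call. = FALSE)
  }
  with_local_seed(cfg$seed, {
    ## baseline homogeneous Poisson process
    n_base <- stats::rpois(1L, cfg$baseline_rate * duration)
    base <- sort(stats::runif(n_base, 0, duration))
    ## multiplicative suppression: thin baseline spikes inside any window
    if (!is.null(pulses) && class_has_in(cfg$response_class) &&
        cfg$inhibition_depth > 0 && length(base)) {
      w0 <- pulses$onset + cfg$inhibition_onset
      w1 <- w0 + cfg$inhibition_duration
      # a spike is inside a window iff the most recent window start not
      # after it has its end beyond it (windows are sorted, may overlap
      # only for pathological configs; nearest-start test is exact for
      # non-overlapping windows)
      idx <- findInterval(base, w0)
      inside <- idx >= 1L & base < w1[pmax(idx, 1L)]
      drop <- inside & stats::runif(length(base)) < cfg$inhibition_depth
      base <- base[!drop]
    }
    ## additive evoked spikes per pulse
    evoked <- numeric()
    if (!is.null(pulses) && class_has_ex(cfg$response_class) &&
        cfg$evoked_extra_spikes > 0) {
      k <- pmin(pulses$pulse_index, length(cfg$depression_factors))
      area <- cfg$evoked_extra_spikes * cfg$depression_factors[k] *
        power_gain_value(cfg, pulses$power_mW)
      n_ev <- stats::rpois(length(area), area)
      if (sum(n_ev)) {
        onset_rep <- rep(pulses$onset, n_ev)
        evoked <- onset_rep + cfg$evoked_latency +
          abs(stats::rnorm(sum(n_ev), 0, cfg$latency_jitter_sd))
      }
    }
    spikes <- sort(c(base, evoked))
    spikes <- spikes[spikes >= 0 & spikes <= duration]
    spike_train(spikes, duration = duration, unit_id = unit_id)
  })
}

#' Ground-truth rate function of a simulated unit
#'
#' Returns the instantaneous-rate function (events/s) that
#' [simulate_spike_train()] draws from, for checking expected spike counts
#' in arbitrary windows against numeric quadrature.
#'
#' @inheritParams simulate_spike_train
#' @return a vectorized function of time (s) returning the rate in Hz.
#' @export
unit_rate_function <- function(cfg, protocol) {
  stopifnot(inherits(cfg, "sim_unit_config"),
            inherits(protocol, "stimulus_protocol"))
  pulses <- if (nrow(protocol$events)) pulse_onsets(protocol) else NULL
  function(t) {
    rate <- rep(cfg$baseline_rate, length(t))
    if (is.null(pulses)) return(rate)
    if (class_has_in(cfg$response_class) && cfg$inhibition_depth > 0) {
      w0 <- pulses$onset + cfg$inhibition_onset
      idx <- findInterval(t, w0)
      inside <- idx >= 1L & t < (w0 + cfg$inhibition_duration)[pmax(idx, 1L)]
      rate[inside] <- rate[inside] * (1 - cfg$inhibition_depth)
    }
    if (class_has_ex(cfg$response_class) && cfg$evoked_extra_spikes > 0) {
      k <- pmin(pulses$pulse_index, length(cfg$depression_factors))
      area <- cfg$evoked_extra_spikes * cfg$depression_factors[k] *
        power_gain_value(cfg, pulses$power_mW)
      for (j in seq_along(pulses$onset)) {
        dt <- t - (pulses$onset[j] + cfg$evoked_latency)
        pos <- dt >= 0
        if (any(pos)) {
          rate[pos] <- rate[pos] + area[j] *
            2 * stats::dnorm(dt[pos], 0, cfg$latency_jitter_sd)
        }
      }
    }
    rate
  }
}

#' Simulate a cohort of units with known ground truth
#'
#' Generates one simulated unit per requested cell, with per-class parameter
#' defaults and ground-truth labels returned alongside, for classifier- and
#' summary-recovery testing. Each unit gets a private RNG stream derived from
#' `(seed, unit index)`, so a cohort regenerates identically unit by unit.
#'
#' Per-class baseline defaults: `Ex` and `NR` 10 Hz; `Ex+In` and `In` 40 Hz.
#' The inhibition signature (three consecutive PSTH bins below mean - SD)
#' is floor-limited — undetectable in principle — unless the expected
#' baseline count per bin exceeds its SD, which at 2-ms bins and 40 trials
#' requires a baseline above roughly 13 Hz, so inhibition-bearing classes
#' are simulated as tonically active units.
#'
#' @param class_counts named vector/list mapping labels (`Ex`, `Ex+In`,
#'   `In`, `NR`) to non-negative unit counts.
#' @param protocol a [stimulus_protocol()] applied to every unit.
#' @param seed master integer seed.
#' @param cfg_template named list of [sim_unit_config()] arguments applied to
#'   every unit on top of the class defaults.
#' @param class_overrides optional named list (per label) of argument lists
#'   overriding the class defaults.
#' @return list with one element per unit:
#'   `list(train =, protocol =, truth = list(label =, cfg =))`.
#' @export
make_cohort <- function(class_counts, protocol, seed,
                        cfg_template = list(), class_overrides = list()) {
  labels <- names(class_counts)
  if (is.null(labels) || !all(labels %in% c("Ex", "Ex+In", "In", "NR"))) {
    stop("class_counts must be named with labels Ex, Ex+In, In, NR",
         call. = FALSE)
  }
  counts <- as.integer(unlist(class_counts))
  if (any(counts < 0)) stop("class counts must be >= 0", call. = FALSE)
  class_defaults <- list(
    "Ex"    = list(baseline_rate = 10),
    "Ex+In" = list(baseline_rate = 40, inhibition_onset = 0.008),
    "In"    = list(baseline_rate = 40, inhibition_onset = 0.003),
    "NR"    = list(baseline_rate = 10)
  )
  out <- vector("list", sum(counts))
  u <- 0L
  for (i in seq_along(labels)) {
    lab <- labels[i]
    for (j in seq_len(counts[i])) {
      u <- u + 1L
      args <- utils::modifyList(
        utils::modifyList(class_defaults[[lab]], cfg_template),
        class_overrides[[lab]] %||% list()
      )
      args$response_class <- lab
      args$seed <- derive_seed(seed, u)
      cfg <- do.call(sim_unit_config, args)
      id <- sprintf("%s_%03d", gsub("\\+", "", lab), u)
      out[[u]] <- list(
        train = simulate_spike_train(cfg, protocol, unit_id = id),
        protocol = protocol,
        truth = list(label = lab, cfg = cfg)
      )
    }
  }
  out
}
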