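#' Configuration of simulated voltage-clamp sweeps
#'
#' Parameters of the generative model for synthetic EPSC sweeps. Each light
#' pulse evokes an inward (negative) difference-of-exponentials current,
#' pre-normalized so that its peak magnitude equals `epsc_amplitude` times
#' the pulse's depression factor. On top of the EPSCs the trace carries a
#' constant holding current, an optional sinusoidal component emulating the
#' subthreshold membrane oscillation of inferior olive neurons (gap-junction
#' coupled cells oscillate at a few Hz), and white Gaussian noise.
#'
#' @param epsc_amplitude first-pulse peak amplitude, pA (magnitude of the
#'   inward deflection).
#' @param rise_tau,decay_tau kernel time constants, s; `rise_tau < decay_tau`.
#' @param noise_sd white-noise SD per sample, pA (>= 0).
#' @param depression_factors five multipliers in `(0, 1]`, first = 1,
#'   scaling the amplitudes of pulses 1..5.
#' @param oscillation_amplitude,oscillation_freq subthreshold oscillation
#'   amplitude (pA) and frequency (Hz); amplitude 0 disables it. Each sweep
#'   draws a uniform random oscillation phase.
#' @param holding_baseline holding current, pA.
#' @param sampling_rate Hz (default 10000).
#' @param seed integer seed, or `NULL`.
#' @return object of class `sim_sweep_config`.
#' @export
sim_sweep_config <- function(epsc_amplitude = 150,
                             rise_tau = 0.001,
                             decay_tau = 0.008,
                             noise_sd = 5,
                             depression_factors = rep(1, 5),
                             oscillation_amplitude = 0,
                             oscillation_freq = 3,
                             holding_baseline = -20,
                             sampling_rate = 10000,
                             seed = NULL) {
  stopifnot_scalar(sampling_rate, "sampling_rate", positive = TRUE)
  stopifnot_scalar(noise_sd, "noise_sd", nonneg = TRUE)
  stopifnot_scalar(epsc_amplitude, "epsc_amplitude", nonneg = TRUE)
  if (rise_tau >= decay_tau) stop("rise_tau must be < decay_tau", call. = FALSE)
  if (length(depression_factors) < 1L || depression_factors[1L] != 1) {
    stop("depression_factors[1] must be 1", call. = FALSE)
  }
  structure(
    list(epsc_amplitude = epsc_amplitude, rise_tau = rise_tau,
         decay_tau = decay_tau, noise_sd = noise_sd,
         depression_factors = as.numeric(depression_factors),
         oscillation_amplitude = oscillation_amplitude,
         oscillation_freq = oscillation_freq,
         holding_baseline = holding_baseline,
         sampling_rate = sampling_rate,
         seed = if (is.null(seed)) NULL else as.integer(seed)),
    class = "sim_sweep_config"
  )
}

#' Unit-peak difference-of-exponentials EPSC kernel
#'
#' `exp(-t/decay) - exp(-t/rise)` for `t >= 0`, scaled so its maximum is
#' exactly 1 (the closed-form peak is at
#' `t* = rise*decay/(decay-rise) * log(decay/rise)`).
#'
#' @param t time since pulse onset, s (vectorized; negative times give 0).
#' @param rise_tau,decay_tau time constants, s.
#' @return kernel values in `[0, 1]`.
#' @export
epsc_kernel <- function(t, rise_tau, decay_tau) {
  t_peak <- rise_tau * decay_tau / (decay_tau - rise_tau) *
    log(decay_tau / rise_tau)
  peak <- exp(-t_peak / decay_tau) - exp(-t_peak / rise_tau)
  out <- numeric(length(t))
  pos <- t >= 0
  out[pos] <- (exp(-t[pos] / decay_tau) - exp(-t[pos] / rise_tau)) / peak
  out
}

#' Simulate a voltage-clamp sweep
#'
#' Builds `holding_baseline + oscillation + noise` minus the superposed
#' per-pulse EPSC kernels (inward currents are negative deflections), each
#' scaled by `epsc_amplitude * depression_factors[k]`.
#'
#' @param cfg a [sim_sweep_config()].
#' @param pulse_times sorted pulse onsets, s. Spacing below one sample
#'   interval is rejected.
#' @param duration sweep length, s; default extends 10 decay constants past
#'   the last pulse.
#' @return a [vc_sweep()].
#' @export
simulate_sweep <- function(cfg, pulse_times, duration = NULL) {
  stopifnot(inherits(cfg, "sim_sweep_config"))
  pulse_times <- as.numeric(pulse_times)
  if (is.unsorted(pulse_times)) stop("pulse_times must be sorted", call. = FALSE)
  if (length(pulse_times) > 1L &&
      min(diff(pulse_times)) < 1 / cfg$sampling_rate) {
    stop("pulse spacing is shorter than one sample interval", call. = FALSE)
  }
  if (is.null(duration)) {
    duration <- (if (length(pulse_times)) max(pulse_times) else 0) +
      10 * cfg$decay_tau + 0.05
  }
  n <- floor(duration * cfg$sampling_rate)
  t <- (seq_len(n) - 1L) / cfg$sampling_rate
  with_local_seed(cfg$seed, {
    trace <- rep(cfg$holding_baseline, n)
    for (j in seq_along(pulse_times)) {
      k <- min(j, length(cfg$depression_factors))
      trace <- trace - cfg$epsc_amplitude * cfg$depression_factors[k] *
        epsc_kernel(t - pulse_times[j], cfg$rise_tau, cfg$decay_tau)
    }
    if (cfg$oscillation_amplitude != 0) {
      phase <- stats::runif(1L, 0, 2 * pi)
      trace <- trace + cfg$oscillation_amplitude *
        sin(2 * pi * cfg$oscillation_freq * t + phase)
    }
    if (cfg$noise_sd > 0) {
      trace <- trace + stats::rnorm(n, 0, cfg$noise_sd)
    }
    vc_sweep(trace, sampling_rate = cfg$sampling_rate,
             pulse_times = pulse_times,
             holding_potential = -60)
  })
}
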