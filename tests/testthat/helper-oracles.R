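# Independent brute-force oracles, deliberately naive: plain loops with the
# same half-open [start, end) window semantics as the package contracts.

# O(n * m) spike tally in aligned bins.
oracle_psth_counts <- function(spike_times, onsets, bin_width, n_pre, n_post) {
  counts <- numeric(n_pre + n_post)
  starts <- ((seq_len(n_pre + n_post) - 1) - n_pre) * bin_width
  for (o in onsets) {
    for (s in spike_times) {
      for (k in seq_along(starts)) {
        if (s - o >= starts[k] && s - o < starts[k] + bin_width) {
          counts[k] <- counts[k] + 1
        }
      }
    }
  }
  counts
}

# Per-trial loop version of the extra-spikes statistic.
oracle_extra_spikes <- function(spike_times, onsets, baseline_rate, window) {
  per_trial <- vapply(onsets, function(o) {
    sum(spike_times >= o & spike_times < o + window)
  }, numeric(1))
  mean(per_trial) - baseline_rate * window
}

# Standard excitatory-unit recording: single pulses every 5 s.
sim_ex_unit <- function(seed, n_trials = 40, baseline = 10, latency = 0.0024,
                        jitter = 0.0003, extra = 1, ...) {
  proto <- single_pulse_protocol(n_events = n_trials)
  cfg <- sim_unit_config(baseline_rate = baseline, response_class = "Ex",
                         evoked_latency = latency, latency_jitter_sd = jitter,
                         evoked_extra_spikes = extra, seed = seed, ...)
  list(train = simulate_spike_train(cfg, proto), protocol = proto, cfg = cfg)
}
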