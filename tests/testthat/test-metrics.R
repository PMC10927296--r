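test_that("extra spikes follow the defining arithmetic", {
  # exactly one spike per trial inside the 30-ms window, 10-Hz baseline:
  # 1 - 10 * 0.03 = 0.7
  onsets <- (1:40) * 5
  st <- spike_train(onsets + 0.002, duration = 210)
  expect_equal(extra_spikes(st, onsets, baseline_mean_rate = 10), 0.7)
  # window is half-open: a spike exactly at onset + window is excluded
  st2 <- spike_train(onsets + 0.030, duration = 210)
  expect_equal(extra_spikes(st2, onsets, baseline_mean_rate = 0), 0)
})

test_that("extra spikes equal the per-trial loop oracle exactly", {
  set.seed(23)
  for (rep in 1:5) {
    spikes <- sort(runif(300, 0, 100))
    onsets <- sort(runif(12, 5, 95))
    b <- runif(1, 0, 20)
    w <- sample(c(0.01, 0.03, 0.05), 1)
    st <- spike_train(spikes, duration = 100)
    expect_identical(extra_spikes(st, onsets, b, window = w),
                     oracle_extra_spikes(spikes, onsets, b, w))
  }
})

test_that("extra spikes are ~0 under the homogeneous Poisson null", {
  vals <- vapply(1:200, function(s) {
    proto <- single_pulse_protocol(n_events = 20)
    cfg <- sim_unit_config(baseline_rate = 15, response_class = "NR",
                           seed = 3000 + s)
    st <- simulate_spike_train(cfg, proto)
    extra_spikes(st, proto$events$onset,
                 baseline_rate_before(st, proto$events$onset))
  }, numeric(1))
  sem <- sd(vals) / sqrt(length(vals))
  expect_lt(abs(mean(vals)), 3 * sem + 1e-9)
})

test_that("extra spikes are additive in the evoked kernel area", {
  recover <- function(extra, seed) {
    u <- sim_ex_unit(seed = seed, n_trials = 400, extra = extra)
    extra_spikes(u$train, u$protocol$events$onset,
                 baseline_rate_before(u$train, u$protocol$events$onset))
  }
  e1 <- recover(0.75, seed = 91)
  e2 <- recover(1.50, seed = 92)
  # Poisson counting error of e2 - 2 * e1 at 400 trials
  se <- sqrt(4 * (0.75 + 0.3) / 400 + (1.5 + 0.3) / 400)
  expect_lt(abs(e2 - 2 * e1), 3 * se)
})

test_that("train profiles reproduce the normalization arithmetic", {
  # per-pulse responses in exact ratios via deterministic spike placement:
  # pulse k of each train receives spikes only when its index allows
  onsets <- (0:9) * 10 + 5
  per_pulse_counts <- c(10, 9, 8, 8, 8)  # of 10 trains
  spikes <- sort(unlist(lapply(1:5, function(k) {
    (onsets + (k - 1) * 0.05 + 0.002)[seq_len(per_pulse_counts[k])]
  })))
  st <- spike_train(spikes, duration = 120)
  prof <- train_profile(st, onsets, baseline_mean_rate = 0)
  expect_equal(prof$per_pulse_extra_spikes, c(1, .9, .8, .8, .8))
  expect_equal(prof$normalized[1], 1)
  expect_equal(prof$depression_1_to_2, 10)
  expect_equal(prof$depression_1_to_last, 20, tolerance = 1e-9)
})

test_that("constant per-pulse responses give zero depression", {
  onsets <- (0:9) * 10 + 5
  spikes <- sort(unlist(lapply(0:4, function(k) onsets + k * 0.05 + 0.003)))
  st <- spike_train(spikes, duration = 120)
  prof <- train_profile(st, onsets, baseline_mean_rate = 0)
  expect_equal(prof$depression_1_to_2, 0)
  expect_equal(prof$depression_1_to_last, 0)
})

test_that("train profiles accept protocols and recover depression factors", {
  proto <- train_protocol(n_events = 400)
  f <- c(1, 0.9, 0.85, 0.8, 0.75)
  cfg <- sim_unit_config(baseline_rate = 10, response_class = "Ex",
                         depression_factors = f, seed = 61)
  st <- simulate_spike_train(cfg, proto)
  prof <- train_profile(st, proto)
  expect_equal(prof$n_trains, 400)
  # per-pulse ratio SD ~0.075 at 400 trains; 3-sigma envelope
  expect_lt(max(abs(prof$normalized - f)), 0.23)
})

test_that("normalized profiles at 40 trains are nearly unbiased for the factors", {
  # bias of the pulse-k/pulse-1 ratio across seeds; the small positive bias
  # from the noisy denominator stays well inside 0.05
  proto <- train_protocol(n_events = 40)
  f <- c(1, 0.9, 0.85, 0.8, 0.75)
  norm <- vapply(1:300, function(s) {
    cfg <- sim_unit_config(baseline_rate = 10, response_class = "Ex",
                           depression_factors = f, seed = 5000 + s)
    st <- simulate_spike_train(cfg, proto)
    train_profile(st, proto)$normalized
  }, numeric(5))
  bias <- rowMeans(norm) - f
  expect_lt(max(abs(bias)), 0.05)
})

test_that("non-positive first-pulse responses flag the profile", {
  onsets <- (0:4) * 10 + 5
  st <- spike_train(onsets + 0.07, duration = 60)  # spikes only after pulse 2
  prof <- train_profile(st, onsets, baseline_mean_rate = 0)
  expect_true("nonpositive-first-pulse" %in% prof$flags)
  expect_true(all(is.na(prof$normalized)))
  expect_true(is.na(prof$depression_1_to_last))
})

test_that("graded responses normalize to the measured 1-mW response", {
  # deterministic proportional responses at 0.5 / 1 / 2 mW
  powers <- c(0.5, 1, 2)
  onsets <- 5 + (0:29) * 5
  power_of <- rep(powers, each = 10)
  # k spikes per trial proportional to power: 1, 2, 4
  spikes <- sort(unlist(lapply(seq_along(onsets), function(i) {
    onsets[i] + seq_len(c(1, 2, 4)[match(power_of[i], powers)]) * 0.002
  })))
  st <- spike_train(spikes, duration = 160)
  proto <- stimulus_protocol(onsets, kind = "single", power_mW = power_of)
  g <- graded_response(st, proto, baseline_mean_rate = 0)
  expect_equal(g$powers_mW, powers)
  expect_equal(g$normalized_to_1mW, c(0.5, 1, 2))
  expect_length(g$flags, 0)
})

test_that("graded normalization interpolates when 1 mW was not tested", {
  powers <- c(0.5, 1.5, 3)
  onsets <- 5 + (0:29) * 5
  power_of <- rep(powers, each = 10)
  spikes <- sort(unlist(lapply(seq_along(onsets), function(i) {
    onsets[i] + seq_len(c(1, 3, 6)[match(power_of[i], powers)]) * 0.002
  })))
  st <- spike_train(spikes, duration = 160)
  proto <- stimulus_protocol(onsets, kind = "single", power_mW = power_of)
  g <- graded_response(st, proto, baseline_mean_rate = 0)
  # linear interpolation between (0.5, 1) and (1.5, 3) gives 2 at 1 mW
  expect_equal(g$reference_response, 2)
  expect_equal(g$normalized_to_1mW, c(0.5, 1.5, 3))
})

test_that("one-sided power designs fall back to the nearest power, flagged", {
  powers <- c(2, 4, 8)
  onsets <- 5 + (0:29) * 5
  power_of <- rep(powers, each = 10)
  spikes <- sort(onsets + 0.002)
  st <- spike_train(spikes, duration = 160)
  proto <- stimulus_protocol(onsets, kind = "single", power_mW = power_of)
  g <- graded_response(st, proto, baseline_mean_rate = 0)
  expect_true("nearest-power-reference" %in% g$flags)
})

test_that("graded analysis requires three distinct powers", {
  onsets <- 5 + (0:9) * 5
  proto <- stimulus_protocol(onsets, power_mW = rep(c(1, 2), 5))
  st <- spike_train(onsets + 0.002, duration = 60)
  expect_error(graded_response(st, proto), "three distinct powers")
})
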