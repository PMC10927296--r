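test_that("baseline-only simulation matches the Poisson mean-variance oracle", {
  proto <- stimulus_protocol(numeric())
  cfg <- sim_unit_config(baseline_rate = 10, response_class = "NR", seed = 11)
  st <- simulate_spike_train(cfg, proto, duration = 200)
  n <- length(st$spike_times)
  expect_true(abs(n - 2000) <= 3 * sqrt(2000))
  expect_false(is.unsorted(st$spike_times, strictly = TRUE))
})

test_that("a null-response unit is statistically a homogeneous Poisson process", {
  # with all evoked parameters zero, window counts match baseline_rate with
  # nominal Poisson coverage across seeds
  proto <- single_pulse_protocol(n_events = 20)
  inside <- vapply(1:100, function(s) {
    cfg <- sim_unit_config(baseline_rate = 12, response_class = "NR", seed = s)
    st <- simulate_spike_train(cfg, proto, duration = 110)
    # post-stimulus windows would carry any evoked structure
    n <- sum(vapply(proto$events$onset, function(o)
      sum(st$spike_times >= o & st$spike_times < o + 0.5), numeric(1)))
    mu <- 12 * 0.5 * 20
    abs(n - mu) <= 1.96 * sqrt(mu)
  }, logical(1))
  expect_gte(mean(inside), 0.89)  # 95% nominal, binomial slack over 100 seeds
})

test_that("evoked excitation adds the configured extra spikes per trial", {
  # rate-integral oracle: 30-ms window holds evoked area + baseline * window
  u <- sim_ex_unit(seed = 3, n_trials = 200, baseline = 10, extra = 1)
  counts <- vapply(u$protocol$events$onset, function(o)
    sum(u$train$spike_times >= o & u$train$spike_times < o + 0.03), numeric(1))
  expect_equal(mean(counts), 1.3, tolerance = 3 * sqrt(1.3 / 200) / 1.3)
})

test_that("expected window counts equal the quadrature of the rate function", {
  proto <- single_pulse_protocol(n_events = 6, spacing = 5)
  cfg <- sim_unit_config(baseline_rate = 20, response_class = "Ex+In",
                         evoked_extra_spikes = 1.5, inhibition_onset = 0.008,
                         inhibition_duration = 0.03, inhibition_depth = 0.7,
                         seed = 5)
  rate_fn <- unit_rate_function(cfg, proto)
  windows <- list(c(4.9, 5.1), c(5, 5.003), c(5.005, 5.05), c(0, 35))
  for (w in windows) {
    expected <- stats::integrate(rate_fn, w[1], w[2],
                                 subdivisions = 2000L, rel.tol = 1e-8)$value
    # Monte Carlo mean over repeated draws from the same generative process
    draws <- vapply(1:150, function(s) {
      cfg_s <- sim_unit_config(baseline_rate = 20, response_class = "Ex+In",
                               evoked_extra_spikes = 1.5, inhibition_onset = 0.008,
                               inhibition_duration = 0.03, inhibition_depth = 0.7,
                               seed = 1000 + s)
      st <- simulate_spike_train(cfg_s, proto, duration = 35)
      sum(st$spike_times >= w[1] & st$spike_times < w[2])
    }, numeric(1))
    se <- sd(draws) / sqrt(length(draws))
    expect_true(abs(mean(draws) - expected) <= 4 * max(se, 0.02),
                label = sprintf("window [%g, %g): sim %.3f vs quadrature %.3f",
                                w[1], w[2], mean(draws), expected))
  }
})

test_that("inhibition suppresses the configured fraction of baseline spikes", {
  proto <- single_pulse_protocol(n_events = 100)
  cfg <- sim_unit_config(baseline_rate = 40, response_class = "In",
                         inhibition_onset = 0.003, inhibition_duration = 0.03,
                         inhibition_depth = 0.9, seed = 21)
  st <- simulate_spike_train(cfg, proto)
  inh_counts <- vapply(proto$events$onset, function(o)
    sum(st$spike_times >= o + 0.003 & st$spike_times < o + 0.033), numeric(1))
  mu <- 40 * 0.03 * 0.1  # baseline * duration * (1 - depth)
  expect_true(abs(mean(inh_counts) - mu) <= 3 * sqrt(mu / 100))
})

test_that("simulation is reproducible by seed and varies across seeds", {
  proto <- single_pulse_protocol(n_events = 10)
  cfg1 <- sim_unit_config(seed = 99)
  a <- simulate_spike_train(cfg1, proto)
  b <- simulate_spike_train(cfg1, proto)
  expect_identical(a$spike_times, b$spike_times)
  c_ <- simulate_spike_train(sim_unit_config(seed = 100), proto)
  expect_false(identical(a$spike_times, c_$spike_times))
})

test_that("simulation does not disturb the caller's RNG stream", {
  set.seed(1)
  before <- .Random.seed
  invisible(simulate_spike_train(sim_unit_config(seed = 5),
                                 single_pulse_protocol(n_events = 5)))
  expect_identical(.Random.seed, before)
})

test_that("make_cohort returns the requested composition with ground truth", {
  proto <- single_pulse_protocol(n_events = 10)
  cohort <- make_cohort(c("Ex" = 7, "Ex+In" = 21, "In" = 5, "NR" = 10),
                        proto, seed = 1)
  expect_length(cohort, 43L)
  labels <- vapply(cohort, function(u) u$truth$label, character(1))
  expect_equal(as.vector(table(factor(labels, c("Ex", "Ex+In", "In", "NR")))),
               c(7L, 21L, 5L, 10L))
  # NR units carry no evoked structure
  nr <- cohort[labels == "NR"]
  expect_true(all(vapply(nr, function(u) u$truth$cfg$response_class == "NR",
                         logical(1))))
  # byte-identical regeneration under the same master seed
  cohort2 <- make_cohort(c("Ex" = 7, "Ex+In" = 21, "In" = 5, "NR" = 10),
                         proto, seed = 1)
  expect_identical(lapply(cohort, function(u) u$train$spike_times),
                   lapply(cohort2, function(u) u$train$spike_times))
})

test_that("power gain scales the evoked response proportionally by default", {
  proto <- single_pulse_protocol(n_events = 300, power_mW = 2)
  cfg <- sim_unit_config(baseline_rate = 0, response_class = "Ex",
                         evoked_extra_spikes = 0.5,
                         power_gain = list(reference_mW = 1, exponent = 1),
                         seed = 8)
  st <- simulate_spike_train(cfg, proto)
  # expected 0.5 * (2 mW / 1 mW) = 1 evoked spike per trial
  expect_equal(length(st$spike_times) / 300, 1, tolerance = 3 / sqrt(300))
})

test_that("simulator configs validate their invariants", {
  expect_error(sim_unit_config(baseline_rate = -1), ">= 0")
  expect_error(sim_unit_config(inhibition_depth = 1.2), "\\[0, 1\\]")
  expect_error(sim_unit_config(depression_factors = c(0.9, 1, 1, 1, 1)),
               "must be 1")
  expect_error(sim_unit_config(depression_factors = c(1, 0, 1, 1, 1)),
               "\\(0, 1\\]")
  expect_error(sim_sweep_config(rise_tau = 0.01, decay_tau = 0.005),
               "rise_tau")
  expect_error(sim_sweep_config(noise_sd = -1), ">= 0")
  expect_error(simulate_spike_train(sim_unit_config(seed = 1),
                                    single_pulse_protocol(n_events = 5),
                                    duration = 3),
               "within the recording duration")
})
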