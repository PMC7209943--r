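# Breath segmentation, the two-branch sniff criterion and the
# epoch-conditioned flow comparison.

test_that("segment_breaths recovers constructed breaths", {
  sim <- simulate_airflow(trace_sim_config(duration_s = 40, fs = 25,
                                           breath_period_s = 4, noise_sd = 0))
  br <- segment_breaths(sim$trace)
  expect_equal(nrow(br), 10)
  expect_lt(diff(range(br$volume)) / mean(br$volume), 1e-6)
  expect_true(all(br$offset > br$onset))
  expect_true(all(br$volume >= 0))
  # volumes approximate the analytic half-sine integral A*T/pi
  expect_equal(mean(br$volume), 100 * 4 / pi, tolerance = 0.02)
})

test_that("a flat trace yields no breaths, with a warning", {
  tr <- airflow_trace(rep(0, 500), fs = 25)
  expect_warning(br <- segment_breaths(tr), "flat")
  expect_equal(nrow(br), 0)
})

test_that("noisy segmentation stays within one breath of ground truth", {
  sim <- simulate_airflow(trace_sim_config(duration_s = 60, fs = 25,
                                           breath_period_s = 4,
                                           baseline_amplitude = 100,
                                           noise_sd = 5, seed = 2))
  br <- segment_breaths(sim$trace)
  expect_lte(abs(nrow(br) - 15), 1)
})

test_that("uniform breathing produces no sniff events", {
  sim <- simulate_airflow(trace_sim_config(duration_s = 120, fs = 25,
                                           noise_sd = 0))
  ev <- detect_sniffs(sim$trace, baseline_window = c(0, 60))
  expect_equal(nrow(ev), 0)
})

test_that("an injected +50% event is detected on the volume branch", {
  sim <- simulate_airflow(trace_sim_config(
    duration_s = 120, fs = 25, breath_period_s = 4, noise_sd = 0,
    events = data.frame(onset_s = 89, relative_volume_change = 0.5)))
  ev <- detect_sniffs(sim$trace, baseline_window = c(0, 60))
  expect_equal(nrow(ev), 1)
  expect_equal(ev$branch, "volume")
  expect_equal(ev$direction, "increase")
  expect_equal(ev$norm_change, 0.5, tolerance = 0.01)
})

test_that("decrease events fire symmetrically and sub-threshold ones do not", {
  sim <- simulate_airflow(trace_sim_config(
    duration_s = 120, fs = 25, noise_sd = 0,
    events = data.frame(onset_s = c(81, 101),
                        relative_volume_change = c(-0.4, 0.10))))
  ev <- detect_sniffs(sim$trace, baseline_window = c(0, 60))
  expect_equal(nrow(ev), 1)
  expect_equal(ev$direction, "decrease")

  # +10% with the zscore branch explicitly disabled by zero variance
  sim2 <- simulate_airflow(trace_sim_config(
    duration_s = 120, fs = 25, noise_sd = 0,
    events = data.frame(onset_s = 90, relative_volume_change = 0.10)))
  expect_warning(
    ev2 <- detect_sniffs(sim2$trace, baseline_window = c(0, 60),
                         sd_method = "zscore"),
    "zero variance")
  expect_equal(nrow(ev2), 0)
})

test_that("volume-branch detections are invariant to trace rescaling", {
  sim <- simulate_airflow(trace_sim_config(
    duration_s = 120, fs = 25, noise_sd = 3, seed = 4,
    events = data.frame(onset_s = c(70, 90, 110),
                        relative_volume_change = c(0.3, -0.3, 0.5))))
  ev1 <- detect_sniffs(sim$trace, baseline_window = c(0, 60))
  scaled <- airflow_trace(sim$trace$flow * 7.3, sim$trace$fs)
  ev2 <- detect_sniffs(scaled, baseline_window = c(0, 60))
  expect_equal(ev1$breath, ev2$breath)
  expect_equal(ev1$normalized_volume, ev2$normalized_volume, tolerance = 1e-12)
  expect_equal(ev1$branch, ev2$branch)
})

test_that("baseline breaths are never self-flagged", {
  sim <- simulate_airflow(trace_sim_config(
    duration_s = 120, fs = 25, noise_sd = 5, seed = 6,
    events = data.frame(onset_s = 30, relative_volume_change = 0.5)))
  # the event sits inside the held-out baseline window: nothing flagged
  ev <- detect_sniffs(sim$trace, baseline_window = c(0, 60))
  expect_false(any(ev$t_onset < 60))
})

test_that("the detector needs a usable baseline", {
  sim <- simulate_airflow(trace_sim_config(duration_s = 40, fs = 25))
  expect_error(detect_sniffs(sim$trace, baseline_window = c(0, 5)),
               "at least 3 breaths")
})

test_that("epoch comparison is null for identical flow in both epochs", {
  sim <- simulate_airflow(trace_sim_config(duration_s = 120, fs = 25,
                                           noise_sd = 0))
  tr <- airflow_trace(sim$trace$flow, 25,
                      epochs = data.frame(start_s = c(0, 60),
                                          end_s = c(60, 120),
                                          label = c("baseline", "hand")))
  res <- epoch_flow_comparison(tr)
  expect_equal(res$mean_diff, 0, tolerance = 1e-12)
  expect_equal(res$t, 0)
})

test_that("a constructed x2 hand-epoch flow is recovered", {
  subs <- lapply(1:8, function(i) simulate_epoch_trace(
    trace_sim_config(duration_s = 120, fs = 25, noise_sd = 2, seed = 100 + i),
    hand_epochs = data.frame(start_s = 60, end_s = 100), hand_gain = 2))
  res <- epoch_flow_comparison(subs)
  expect_equal(res$n, 8)
  expect_equal(res$mean_hand / res$mean_baseline, 2, tolerance = 0.05)
  expect_gt(res$t, 0)
  expect_equal(res$df, 7)
  expect_equal(res$n_increase, 8)
})

test_that("epoch comparison is invariant to subject and epoch order", {
  subs <- lapply(1:5, function(i) simulate_epoch_trace(
    trace_sim_config(duration_s = 120, fs = 25, noise_sd = 2, seed = 200 + i),
    hand_epochs = data.frame(start_s = c(60, 90), end_s = c(80, 110)),
    hand_gain = 1.8))
  res1 <- epoch_flow_comparison(subs)
  res2 <- epoch_flow_comparison(rev(subs))
  expect_equal(res1$mean_diff, res2$mean_diff)
  expect_equal(res1$t, res2$t)
  expect_equal(res1$n_increase, res2$n_increase)

  # shuffling epoch rows within a trace changes nothing
  tr <- subs[[1]]
  shuffled <- airflow_trace(tr$flow, tr$fs, tr$epochs[rev(seq_len(nrow(tr$epochs))), ])
  expect_equal(epoch_flow_comparison(list(shuffled))$mean_diff,
               epoch_flow_comparison(list(tr))$mean_diff)
})

test_that("a 12-of-17 increase structure is reported with its exact tail", {
  subs <- lapply(1:17, function(i) simulate_epoch_trace(
    trace_sim_config(duration_s = 80, fs = 25, noise_sd = 0),
    hand_epochs = data.frame(start_s = 40, end_s = 80),
    hand_gain = if (i <= 12) 1.5 else 0.7))
  res <- epoch_flow_comparison(subs)
  expect_equal(res$n_increase, 12)
  expect_equal(res$n, 17)
  expect_equal(res$p_binomial, 9402 / 131072)
})
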