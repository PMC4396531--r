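test_that("identical config and seed give bit-identical recordings", {
  cfg <- synth_config(duration = 200, seed = 4)
  a <- generate_recording(cfg)
  b <- generate_recording(cfg)
  expect_identical(a$spikes$spikes, b$spikes$spikes)
  expect_identical(a$truth$per_stimulus, b$truth$per_stimulus)
  c2 <- generate_recording(cfg, seed = 5)
  expect_false(identical(a$spikes$spikes, c2$spikes$spikes))
})

test_that("the network refractory period is honored exactly", {
  # candidate grid finer than the refractory period: the sequential rule
  # must still keep consecutive NS peaks >= refractory apart
  cfg <- suppressWarnings(
    synth_config(duration = 2000, spontaneous = TRUE, spont_dt_s = 1,
                 spont_rate = 0.4, refractory = 2, seed = 8))
  rec <- suppressWarnings(generate_recording(cfg))
  pk <- rec$truth$ns_peak_times_s
  expect_gt(length(pk), 50)
  expect_true(min(diff(pk)) >= 2)
})

test_that("fractional Gaussian noise has the prescribed covariance", {
  expect_error(fractional_gaussian_noise(100, 1.2), "H must")
  expect_error(fractional_gaussian_noise(100, 0.3), "H must")
  set.seed(2)
  z <- fractional_gaussian_noise(20000, 0.82)
  expect_equal(var(z), 1, tolerance = 0.1)
  r1_theory <- 0.5 * (2^1.64 - 2)
  expect_equal(cor(z[-1], z[-20000]), r1_theory, tolerance = 0.05)
  # reproducibility under the caller's seed
  set.seed(3); a <- fractional_gaussian_noise(64, 0.7)
  set.seed(3); b <- fractional_gaussian_noise(64, 0.7)
  expect_identical(a, b)
})

test_that("an OU latent with a huge time constant degenerates to a constant", {
  cfg <- synth_config(duration = 600, latent_tau_s = 1e9, seed = 6)
  set.seed(6)
  lat <- generate_latent(cfg, 100, 5)
  expect_lt(max(abs(diff(lat$e))), 1e-3)
  expect_lt(max(abs(diff(lat$i))), 1e-3)
})

test_that("latent modes validate their required parameters", {
  expect_error(synth_config(latent_mode = "fgn"), "target_ff_exponent")
  expect_error(synth_config(latent_mode = "fgn", target_ff_exponent = 1.3),
               "target_ff_exponent")
  expect_error(synth_config(latent_mode = "oscillatory"), "osc_period")
  expect_error(synth_config(amplitude = 0.1, rate_floor = 0.15,
                            baseline_rate = 0), "undetectable")
})

test_that("programmed envelopes cross the rate floor at latency + decay", {
  cfg <- synth_config(duration = 60, stim_rate = 1/5, baseline_rate = 0,
                      amplitude = 5, latency_base_ms = 150,
                      latency_gain_ms = 0, decay_base_ms = 250,
                      decay_gain_ms = 0, noise_sd_latency_ms = 0,
                      noise_sd_decay_ms = 0, response_threshold = -Inf,
                      spike_sampling = "deterministic", seed = 1)
  rec <- generate_recording(cfg)
  p <- build_psth(rec$spikes, rec$stims$onsets[1])
  lat <- response_latency(p)
  dec <- decay_duration(p, lat)
  expect_equal(lat, 150, tolerance = 3.5)
  expect_equal(lat + dec$decay_ms, 400, tolerance = 27)
})

test_that("ground truth round-trips through its TSV representation", {
  cfg <- synth_config(duration = 150, seed = 12)
  rec <- generate_recording(cfg)
  p <- tempfile()
  write_truth(rec$truth, p)
  back <- read_truth(p)
  expect_equal(back$per_stimulus, rec$truth$per_stimulus, tolerance = 1e-5)
  expect_equal(back$ns_peak_times_s, rec$truth$ns_peak_times_s,
               tolerance = 1e-5)

  cfg2 <- synth_config(duration = 400, spontaneous = TRUE, seed = 12)
  rec2 <- generate_recording(cfg2)
  write_truth(rec2$truth, p)
  back2 <- read_truth(p)
  expect_equal(nrow(back2$spontaneous), nrow(rec2$truth$spontaneous))
  expect_equal(back2$ns_peak_times_s, sort(rec2$truth$ns_peak_times_s),
               tolerance = 1e-5)
})

test_that("evoked response probability sits near its configured level", {
  cfg <- synth_config(duration = 7200, seed = 21)
  rec <- generate_recording(cfg)
  p_hat <- mean(rec$truth$per_stimulus$responded)
  # threshold qnorm(1 - 0.22) targets 0.22 before refractory censoring
  expect_gt(p_hat, 0.10)
  expect_lt(p_hat, 0.35)
})
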