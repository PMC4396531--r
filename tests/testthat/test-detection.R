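test_that("population rate counts spikes per half-open bin", {
  s <- spike_train_set(c(0L, 1L, 0L), c(0.0005, 0.001, 0.0029),
                       duration = 0.003, n_electrodes = 2L)
  r <- population_rate(s, bin_width_ms = 3)
  expect_equal(r$values[1], 1.0)  # 3 spikes in [0, 3) ms / 3 ms
  # rate integrates back to the total spike count
  s2 <- spike_train_set(rep(0L, 50), sort(runif(50, 0, 0.9)), duration = 1)
  r2 <- population_rate(s2, 3)
  expect_equal(sum(r2$values) * 3, 50)
  expect_length(r2$values, ceiling(1000 / 3))
})

test_that("sub-threshold rate yields no events", {
  s <- pulse_spikes(1, 300, rate = 1/3, duration = 1)  # 0.33 spikes/ms
  ns <- detect_network_spikes(population_rate(s), threshold = 0.5)
  expect_equal(nrow(ns$events), 0L)
})

test_that("a rectangular pulse gives one event with earliest-max peak", {
  s <- pulse_spikes(11, 21, rate = 2, duration = 1)
  ns <- detect_network_spikes(population_rate(s), threshold = 0.15)
  expect_equal(nrow(ns$events), 1L)
  expect_equal(ns$events$onset_time_s, 10 * 0.003)      # left edge of bin 11
  expect_equal(ns$events$peak_time_s, 10.5 * 0.003)     # center of bin 11
  expect_equal(ns$events$peak_rate, 2)
})

test_that("runs closer than the merge window become one event", {
  times <- c(pulse_spikes(11, 13, 2, 1)$spikes$time_s,
             pulse_spikes(48, 50, 2, 1)$spikes$time_s)  # gap ~100 ms
  s <- spike_train_set(rep(0L, length(times)), times, duration = 1)
  one <- detect_network_spikes(population_rate(s), 0.15, merge_window_ms = 150)
  expect_equal(nrow(one$events), 1L)
  two <- detect_network_spikes(population_rate(s), 0.15, merge_window_ms = 50)
  expect_equal(nrow(two$events), 2L)
})

test_that("detection ignores added sub-threshold background", {
  s <- pulse_spikes(101, 110, rate = 2, duration = 2)
  base <- detect_network_spikes(population_rate(s), threshold = 0.5)
  # one background spike per 3 ms bin in a quiet stretch: 0.33 spikes/ms < 0.5
  bg <- seq(1.0015, 1.9, by = 0.003)
  s2 <- spike_train_set(c(s$spikes$electrode_id, rep(1L, length(bg))),
                        c(s$spikes$time_s, bg), duration = 2)
  with_bg <- detect_network_spikes(population_rate(s2), threshold = 0.5)
  expect_equal(with_bg$events, base$events)
})

test_that("stimulus pairing assigns the earliest in-window NS once", {
  stims <- stimulus_train(c(10, 20))
  ns <- ns_train(c(10.15, 10.65, 21.5), rep(2, 3), c(10.1, 10.6, 21.4), 30)
  tab <- pair_stimuli(ns, stims, window_s = 1)
  expect_equal(tab$success, c(TRUE, FALSE))
  expect_equal(tab$ns_peak_time_s[1], 10.15)
  expect_equal(attr(tab, "spontaneous_ns"), c(2L, 3L))
  # conservation: successes + spontaneous = all events
  expect_equal(sum(tab$success) + length(attr(tab, "spontaneous_ns")),
               nrow(ns$events))
})

test_that("pairing warns when stimulus windows overlap", {
  stims <- stimulus_train(c(1, 1.5, 2))
  ns <- ns_train(1.6, 2, 1.55, 3)
  expect_warning(tab <- pair_stimuli(ns, stims, window_s = 1), "window")
  expect_equal(tab$success, c(TRUE, FALSE, FALSE))  # earliest stimulus wins
})

test_that("zero-noise synthetic recordings are detected exactly", {
  cfg <- synth_config(duration = 120, stim_rate = 1/5, baseline_rate = 0,
                      amplitude = 5, response_threshold = -Inf,
                      noise_sd_latency_ms = 0, noise_sd_decay_ms = 0,
                      spike_sampling = "deterministic", seed = 3)
  rec <- generate_recording(cfg)
  ns <- detect_network_spikes(population_rate(rec$spikes), threshold = 0.15)
  expect_equal(nrow(ns$events), length(rec$truth$ns_peak_times_s))
  expect_equal(ns$events$peak_time_s, rec$truth$ns_peak_times_s,
               tolerance = 0.01)
})
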