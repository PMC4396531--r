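test_that("a 5-spike impulse spreads to 1.0 spikes/ms over five 1 ms bins", {
  t0 <- 0.2005  # all five spikes inside bin [200, 201) ms after the stimulus
  s <- spike_train_set(rep(0L, 5), rep(t0, 5) + seq(0, 4e-5, by = 1e-5),
                       duration = 2)
  p <- build_psth(s, stim_time_s = 0)
  expect_equal(p$raw[201], 5)
  expect_equal(p$smooth5[199:203], rep(1, 5))
  expect_equal(sum(p$smooth5), sum(p$raw))  # impulse far from edges
})

test_that("psth rejects windows that overrun the recording", {
  s <- spike_train_set(0L, 0.5, duration = 1)
  expect_error(build_psth(s, stim_time_s = 0.2), "truncated")
  expect_error(build_psth(s, stim_time_s = 0, wide_width_ms = 20), "30")
})

test_that("latency takes the first sufficiently prominent maximum", {
  v <- numeric(1500)
  v[50:150] <- dnorm(50:150, 100, 20)        # single peak at bin 100
  expect_equal(response_latency(fake_psth(v)), 99.5)

  plateau <- numeric(1500)
  plateau[101:105] <- 1                       # plateau at the max, 100-104 ms
  plateau[90:100] <- seq(0.1, 0.9, length.out = 11)
  expect_equal(response_latency(fake_psth(plateau)), 100.5)

  two <- numeric(1500)
  two[81] <- 0.4; two[141] <- 1               # early bump below prominence
  expect_equal(response_latency(fake_psth(two)), 140.5)
  two[81] <- 0.6                              # now prominent: first max wins
  expect_equal(response_latency(fake_psth(two)), 80.5)
  expect_equal(response_latency(fake_psth(two), prominence_frac = "global"),
               140.5)
  expect_error(response_latency(fake_psth(numeric(1500))), "no response")
})

test_that("latency is invariant under uniform rescaling, decay is not", {
  v <- numeric(1500)
  v[80:400] <- c(seq(0.1, 2, length.out = 60), seq(2, 0.01, length.out = 261))
  p1 <- fake_psth(v); p2 <- fake_psth(v * 7)
  expect_equal(response_latency(p1), response_latency(p2))
  l <- response_latency(p1)
  d1 <- decay_duration(p1, l)$decay_ms
  d2 <- decay_duration(p2, l)$decay_ms
  expect_gt(d2, d1)  # higher trace crosses the fixed floor later
})

test_that("decay duration measures the first drop below the floor", {
  v <- numeric(1500)
  v[1:100] <- seq(0, 3, length.out = 100)
  v[101:1500] <- pmax(3 - 0.01425 * (1:1400), 0)  # crosses 0.15 at bin ~300
  l <- 100
  d <- decay_duration(fake_psth(v, v), l)
  expect_false(d$censored)
  expect_equal(d$decay_ms, 200.5, tolerance = 2)

  flat <- rep(0.5, 1500)  # never drops below the floor
  dc <- decay_duration(fake_psth(flat, flat), 100)
  expect_true(dc$censored)
  expect_equal(dc$decay_ms, 1400)

  low <- rep(0.01, 1500)  # already below floor at the latency bin
  expect_message(d0 <- decay_duration(fake_psth(low, low), 100), "floor")
  expect_equal(d0$decay_ms, 0)
  expect_false(d0$censored)
})

test_that("local response probability excludes the index and truncates edges", {
  succ <- rep(TRUE, 21)
  expect_equal(local_response_probability(succ, 11), 1.0)
  succ2 <- rep(c(TRUE, FALSE), length.out = 21)  # 10 successes among 20 nbrs
  expect_equal(local_response_probability(succ2, 11), 0.5)
  edge <- c(TRUE, rep(c(TRUE, TRUE, TRUE, FALSE, FALSE), 2))  # 6/10 after idx 1
  expect_equal(local_response_probability(edge, 1), 0.6)
  # index exclusion: flipping the index stimulus leaves its own value unchanged
  s3 <- succ2; s3[11] <- !s3[11]
  expect_equal(local_response_probability(succ2, 11),
               local_response_probability(s3, 11))
  expect_error(local_response_probability(TRUE, 1), "2 stimuli")
})

test_that("moving averages conserve mass up to edge truncation", {
  set.seed(42)
  for (w in c(5, 51)) {
    x <- rpois(1500, 0.8)
    sm <- moving_average(x, w)
    expect_gte(sum(sm), sum(x) * (1 - w / 1500))
    expect_lte(sum(sm), sum(x) + 1e-9)
  }
})

test_that("programmed zero-noise features are recovered end to end", {
  cfg <- synth_config(duration = 220, stim_rate = 1/5, baseline_rate = 0,
                      amplitude = 10, rise_sd_ms = 10,
                      latency_base_ms = 120, latency_gain_ms = 0,
                      decay_base_ms = 300, decay_gain_ms = 0,
                      noise_sd_latency_ms = 0, noise_sd_decay_ms = 0,
                      response_threshold = -Inf,
                      spike_sampling = "deterministic", seed = 9)
  rec <- generate_recording(cfg)
  ns <- detect_network_spikes(population_rate(rec$spikes), threshold = 0.15)
  tab <- add_response_features(rec$spikes, pair_stimuli(ns, rec$stims))
  ok <- tab$success & !is.na(tab$latency_ms)
  expect_gt(sum(ok), 30)
  expect_true(all(abs(tab$latency_ms[ok] - 120) <= 3.5))   # bin + half window
  expect_true(all(abs(tab$decay_ms[ok] - 300) <= 26))      # wide/2 + bin
})
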