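test_that("the serial autocorrelation matches its printed-form oracle", {
  a <- serial_autocorrelation(c(1, 2, 3, 4), max_lag = 1)
  expect_equal(a$rho[1], 1)          # lag 0 by definition
  expect_equal(a$rho[2], 0.25)       # 1.25 / 5, hand-evaluated
  expect_error(serial_autocorrelation(rep(2, 10), max_lag = 2), "degenerate")
  expect_error(serial_autocorrelation(c(1, 2, 3), max_lag = 5), "too short")
})

test_that("rho stays within [-1, 1] with rho[0] = 1 on random series", {
  set.seed(101)
  for (rep in 1:20) {
    x <- cumsum(rnorm(60))  # strongly autocorrelated random walk
    a <- serial_autocorrelation(x, max_lag = 30)
    expect_equal(a$rho[1], 1)
    expect_true(all(abs(a$rho) <= 1 + 1e-12))
  }
})

test_that("exchangeable series have near-zero autocorrelations", {
  set.seed(13)
  x <- sample(rexp(400))
  a <- serial_autocorrelation(x, max_lag = 100)
  inside <- abs(a$rho[-1]) <= 2 / sqrt(400)
  expect_gte(mean(inside), 0.90)
})

test_that("warped lags scale by the mean inter-response interval", {
  expect_equal(warped_time_axis(seq(0, 100, by = 5), c(0, 10)), c(0, 50))
  expect_equal(warped_time_axis(c(0, 4, 14), 1), 7)
  expect_error(warped_time_axis(3, 1), "2 response")
})

test_that("trajectories are built from successes and segmented by 50", {
  n <- 120
  tab <- response_table(seq(5, by = 5, length.out = n), rep(TRUE, n),
                        latency_ms = rep(100, n), decay_ms = rep(200, n),
                        censored_decay = rep(FALSE, n))
  traj <- build_trajectory(tab)
  expect_equal(nrow(traj$points), 120)
  expect_equal(traj$smoothed$latency_ms, rep(100, n))  # constants unchanged
  expect_length(traj$segments, 2)
  expect_equal(traj$segments[[1]], 1:50)
  expect_equal(traj$segments[[2]], 51:100)
})

test_that("smoothing commutes with affine maps of each coordinate", {
  set.seed(5)
  x <- rnorm(80, 100, 20)
  sm <- moving_average(x, 11)
  expect_equal(moving_average(3 * x + 7, 11), 3 * sm + 7)
})

test_that("censored decays are excluded by default", {
  tab <- response_table(c(5, 10, 15, 20), rep(TRUE, 4),
                        latency_ms = c(100, 110, 120, 130),
                        decay_ms = c(200, 210, 220, 230),
                        censored_decay = c(FALSE, TRUE, FALSE, FALSE))
  expect_warning(traj <- build_trajectory(tab, smooth_window = 11), "window")
  expect_equal(nrow(traj$points), 3)
  traj2 <- suppressWarnings(build_trajectory(tab, drop_censored = FALSE))
  expect_equal(nrow(traj2$points), 4)
})

test_that("the plane center of mass is a geometric mean on the log plane", {
  tab <- response_table(c(5, 10), c(TRUE, TRUE),
                        latency_ms = c(10, 1000), decay_ms = c(10, 1000),
                        censored_decay = c(FALSE, FALSE))
  traj <- suppressWarnings(build_trajectory(tab))
  expect_equal(plane_center_of_mass(traj),
               c(latency_ms = 100, decay_ms = 100))
  expect_equal(plane_center_of_mass(traj, log_plane = FALSE),
               c(latency_ms = 505, decay_ms = 505))
  one <- response_table(5, TRUE, latency_ms = 100, decay_ms = 200,
                        censored_decay = FALSE)
  t1 <- suppressWarnings(build_trajectory(one))
  expect_equal(plane_center_of_mass(t1), c(latency_ms = 100, decay_ms = 200))
  empty <- response_table(numeric(0), logical(0))
  expect_error(plane_center_of_mass(suppressWarnings(build_trajectory(empty))),
               "empty")
})

test_that("an oscillating latent leaves an ACF peak at its period", {
  cfg <- synth_config(duration = 3020, stim_rate = 1/3,
                      latent_mode = "oscillatory", osc_period_responses = 60,
                      response_threshold = -Inf, noise_sd_latency_ms = 2,
                      seed = 101)
  rec <- generate_recording(cfg)
  lat_series <- rec$truth$per_stimulus$true_latency_ms
  a <- serial_autocorrelation(lat_series, max_lag = 90)
  peak <- which.max(a$rho[31:90]) + 29  # first non-trivial local max region
  expect_true(abs(peak - 60) <= 6)
})
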