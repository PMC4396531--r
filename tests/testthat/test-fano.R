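test_that("count sequences bin events into complete windows from t = 0", {
  ns <- ns_from_times(c(1, 2, 3, 11, 12), duration = 20)
  expect_equal(count_sequence(ns, 10), c(3L, 2L))
  expect_equal(count_sequence(ns, 10), count_sequence(ns, 20 / 2))  # boundary
  expect_error(count_sequence(ns, 15), "T too large")
  empty <- ns_train(numeric(0), numeric(0), numeric(0), 20)
  expect_equal(count_sequence(empty, 5), rep(0L, 4))
})

test_that("the worked five-event Fano factor matches hand computation", {
  ns <- ns_from_times(c(1, 2, 3, 11, 12), duration = 20)
  z <- count_sequence(ns, 10)
  expect_equal(var(z) / mean(z), 0.2)  # counts (3,2): mean 2.5, var 0.5
})

test_that("a perfectly periodic train has zero Fano factor at its period", {
  ns <- ns_from_times(seq(0.5, 999.5, by = 1), duration = 1000)
  z <- count_sequence(ns, 10)  # exact multiple of the 1 s period
  expect_equal(var(z), 0)
})

test_that("a homogeneous Poisson train keeps FF near 1", {
  set.seed(7)
  t <- cumsum(rexp(9000, 1))
  ns <- ns_from_times(t[t < 7200], duration = 7200)
  cv <- fano_curve(ns, T_min = 0.05, T_max = 50)
  expect_true(all(abs(cv$ff - 1) < 3 * sqrt(2 / cv$n_windows) + 0.02))
})

test_that("interval shuffling preserves span, count and interval multiset", {
  ns <- ns_from_times(c(1, 2, 4), duration = 10)
  hit <- replicate(50, {
    s <- shuffle_surrogate(ns, seed = sample.int(1e6, 1))$events$peak_time_s
    expect_equal(s[1], 1)
    expect_equal(s[3], 4)
    expect_equal(sort(diff(s)), c(1, 2))
    paste(s, collapse = ",")
  })
  expect_setequal(unique(hit), c("1,2,4", "1,3,4"))
  # seeding contract
  ns2 <- ns_from_times(sort(runif(100, 0, 500)), duration = 500)
  a <- shuffle_surrogate(ns2, seed = 11)
  b <- shuffle_surrogate(ns2, seed = 11)
  expect_identical(a$events, b$events)
  expect_error(shuffle_surrogate(ns_from_times(c(1, 2), 5)), "3 events")
})

test_that("power-law fitting inverts exact power laws to machine precision", {
  T_grid <- 10^seq(0, 2, length.out = 20)
  curve <- structure(list(T_s = T_grid, ff = 3 * T_grid^0.5,
                          n_windows = rep(100, 20)), class = "fano_curve")
  fit <- fit_powerlaw(curve)
  expect_equal(fit$beta, 0.5, tolerance = 1e-10)
  expect_equal(fit$alpha, 3, tolerance = 1e-10)

  unit <- structure(list(T_s = T_grid, ff = T_grid,
                         n_windows = rep(100, 20)), class = "fano_curve")
  fu <- fit_powerlaw(unit)
  expect_equal(fu$beta, 1, tolerance = 1e-10)
  expect_equal(fu$alpha, 1, tolerance = 1e-10)

  flat <- structure(list(T_s = T_grid, ff = rep(2.5, 20),
                         n_windows = rep(100, 20)), class = "fano_curve")
  ff <- fit_powerlaw(flat)
  expect_equal(ff$beta, 0, tolerance = 1e-12)
  expect_equal(ff$alpha, 2.5, tolerance = 1e-10)

  # explicit range override restricts the points used
  fr <- fit_powerlaw(curve, fit_range = c(10, 100))
  expect_equal(fr$fit_range, c(T_lo = 10, T_hi = 100))
  expect_equal(fr$beta, 0.5, tolerance = 1e-10)
  expect_error(fit_powerlaw(structure(list(T_s = T_grid[1:4],
                                           ff = T_grid[1:4],
                                           n_windows = rep(10, 4)),
                                      class = "fano_curve")),
               "5 points")
})

test_that("fano_curve drops sparse window sizes and validates the grid", {
  ns <- ns_from_times(sort(runif(200, 0, 1000)), duration = 1000)
  cv <- fano_curve(ns, T_min = 0.5, T_max = 100, min_windows = 10)
  expect_true(all(cv$n_windows >= 10))
  expect_true(all(diff(cv$T_s) > 0))
  expect_error(fano_curve(ns, T_min = 0.5, T_max = 500, min_windows = 10),
               "duration/min_windows")
})
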