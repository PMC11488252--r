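test_that("noiseless exponential decay is recovered exactly", {
  t <- c(0, 15, 30, 45, 60)
  fit <- fit_first_order_decay(t, 100 * exp(-0.01 * t))
  expect_equal(fit$kd, 0.01, tolerance = 1e-10)
  expect_equal(fit$r_squared, 1)
  expect_equal(fit$n_points, 5L)
  expect_true(fit$decaying)
})

test_that("the two-point fit matches the closed-form slope", {
  fit <- fit_first_order_decay(c(0, 60), c(100, 50))
  expect_equal(fit$kd, log(2) / 60)
  expect_equal(fit$r_squared, 1)
  expect_equal(fit$half_life_min, 60)
})

test_that("noisy synthetic decay recovers kd within the design tolerance", {
  sim <- simulate_thermal_series(kd = c(`50` = 0.005),
                                 times_min = seq(0, 60, by = 12),
                                 noise = "lognormal", noise_sd = 0.05,
                                 seed = 42)
  fit <- fit_first_order_decay(sim$time_min, sim$residual_pct)
  expect_lt(abs(fit$kd - 0.005) / 0.005, 0.15)
})

test_that("decay fitting validates its inputs", {
  expect_error(fit_first_order_decay(c(0, 10), c(100, NA)), "finite")
  expect_error(fit_first_order_decay(c(10, 5), c(90, 80)), "increasing")
  expect_error(fit_first_order_decay(c(-1, 5), c(100, 80)), ">= 0")
  expect_error(fit_first_order_decay(0, 100), "insufficient")
  # non-positive residuals are excluded with a warning, not an error
  expect_warning(
    fit <- fit_first_order_decay(c(0, 30, 60), c(100, 50, 0)),
    "excluded"
  )
  expect_equal(fit$n_points, 2L)
  expect_error(
    suppressWarnings(fit_first_order_decay(c(0, 30), c(100, 0))),
    "insufficient"
  )
})

test_that("a non-decaying series is flagged rather than fitted", {
  fit <- fit_first_order_decay(c(0, 30, 60), c(100, 110, 121))
  expect_false(fit$decaying)
  expect_true(is.na(fit$kd))
  expect_true(is.na(fit$half_life_min))
})

test_that("kd is invariant to rescaling the activity units", {
  t <- c(0, 10, 20, 40, 80)
  y <- 100 * exp(-0.02 * t) * exp(c(0.01, -0.02, 0.015, 0, -0.01))
  f1 <- fit_first_order_decay(t, y)
  f2 <- fit_first_order_decay(t, 3.7 * y)
  expect_equal(f1$kd, f2$kd)
  expect_equal(f2$intercept - f1$intercept, log(3.7))
})

test_that("half-life and D-value follow their closed forms", {
  expect_equal(half_life(log(2)), 1)
  expect_equal(d_value(log(10)), 1)
  # values implied by the published 50-60 degC thermo summary
  expect_equal(round(half_life(log(10) / 718)), 216)
  expect_equal(round(d_value(log(2) / 182)), 605)
  expect_equal(round(d_value(log(2) / 192)), 638)
  expect_equal(half_life(0.0052116), 133.0, tolerance = 1e-3)
  expect_error(half_life(0), "kd")
  expect_error(d_value(-1), "kd")
})

test_that("D/half-life ratio is log2(10) for every fit", {
  set.seed(21)
  for (i in 1:20) {
    t <- sort(sample(0:120, 6))
    y <- 100 * exp(-runif(1, 0.001, 0.05) * t) *
      exp(rnorm(6, 0, 0.05))
    fit <- fit_first_order_decay(t, y)
    expect_equal(fit$d_value_min / fit$half_life_min, log2(10))
    expect_equal(fit$half_life_min, log(2) / fit$kd)
    expect_equal(fit$d_value_min, log(10) / fit$kd)
  }
})

test_that("first-order decay is multiplicative over time on noiseless data", {
  kd <- 0.013
  res <- function(t) 100 * exp(-kd * t)
  t1 <- 17; t2 <- 29
  expect_equal(res(t1 + t2) / 100, res(t1) / 100 * res(t2) / 100)
})

test_that("the consistency checker flags rounding-inconsistent pairs", {
  chk <- check_kinetic_pair(c(238, 182, 133), c(793, 605, 442))
  # 238 -> expected 790.6, printed 793: off by > 2 min
  expect_false(chk$consistent[1])
  expect_gt(abs(chk$deviation_min[1]), 2)
  expect_true(all(chk$consistent[2:3]))
  expect_equal(chk$expected_d_min, log2(10) * c(238, 182, 133))
})

test_that("summarize_inactivation returns one ordered row per series", {
  kd <- c(`50` = 0.002, `55` = 0.003, `60` = 0.005)
  sim <- simulate_thermal_series(kd = kd, times_min = c(0, 15, 30, 45, 60))
  tab <- summarize_inactivation(sim)
  expect_equal(nrow(tab), 3L)
  expect_equal(tab$temperature_C, c(50, 55, 60))
  expect_equal(tab$half_life_min, log(2) / unname(kd), tolerance = 1e-10)
  expect_equal(tab$d_value_min, log(10) / unname(kd), tolerance = 1e-10)
  # kd rises with temperature on decay-law data
  expect_true(all(diff(tab$kd) > 0))
})

test_that("summarize_inactivation pools replicates and handles empties", {
  sim <- simulate_thermal_series(kd = c(`55` = 0.004),
                                 times_min = c(0, 20, 40, 60),
                                 noise = "lognormal", noise_sd = 0.03,
                                 n_replicates = 3L, seed = 9)
  tab <- summarize_inactivation(sim)
  expect_equal(nrow(tab), 1L)
  expect_true(abs(tab$kd - 0.004) / 0.004 < 0.25)
  expect_warning(empty <- summarize_inactivation(sim[0, ]), "empty")
  expect_equal(nrow(empty), 0L)
  # fit failures name the offending series
  bad <- data.frame(form = "free", temperature_C = 50,
                    time_min = 0, residual_pct = 100)
  expect_error(summarize_inactivation(bad), "temperature=50")
})

test_that("interconversion reproduces the published thermo summary table", {
  ts <- fixture_table("thermo_summary")
  # D implied by each printed half-life
  expect_equal(round(d_value(log(2) / ts$half_life_min)),
               c(791, 605, 442, 718, 638, 545))
  # half-life implied by each printed D-value
  expect_equal(round(half_life(log(10) / ts$d_value_min)),
               c(239, 182, 133, 216, 192, 165))
})
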