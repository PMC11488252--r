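test_that("noiseless decay series follow the exponential exactly", {
  sim <- simulate_thermal_series(kd = c(`50` = 0.01),
                                 times_min = c(0, 30, 60))
  expect_equal(sim$residual_pct, 100 * exp(-0.01 * c(0, 30, 60)))
  expect_equal(round(sim$residual_pct, 2), c(100, 74.08, 54.88))
})

test_that("round trip at zero noise recovers the generating kd exactly", {
  kd <- c(`40` = 0.0007, `50` = 0.003, `60` = 0.02)
  sim <- simulate_thermal_series(kd = kd, times_min = c(0, 10, 25, 45, 70))
  tab <- summarize_inactivation(sim)
  expect_equal(tab$kd, unname(kd), tolerance = 1e-12)
  expect_equal(attr(sim, "true_kd"), kd)
})

test_that("an Arrhenius-law config round-trips end to end", {
  sim <- simulate_thermal_series(A = 1e6, E_kJ_mol = 50,
                                 temperatures_C = c(50, 55, 60),
                                 times_min = c(0, 15, 30, 45, 60))
  tab <- summarize_inactivation(sim)
  fit <- fit_arrhenius(celsius_to_kelvin(tab$temperature_C), tab$kd,
                       mode = "deactivation")
  expect_equal(fit$energy_kJ_mol, 50, tolerance = 1e-6)
})

test_that("simulation is deterministic under a fixed seed", {
  cfg <- function() simulate_thermal_series(kd = c(`55` = 0.004),
                                            times_min = c(0, 20, 40),
                                            noise = "lognormal",
                                            noise_sd = 0.1, seed = 123)
  expect_identical(cfg(), cfg())
  other <- simulate_thermal_series(kd = c(`55` = 0.004),
                                   times_min = c(0, 20, 40),
                                   noise = "lognormal", noise_sd = 0.1,
                                   seed = 124)
  expect_false(identical(cfg()$residual_pct, other$residual_pct))
  # the caller's RNG stream is not consumed
  set.seed(1); before <- runif(1)
  set.seed(1); invisible(cfg()); after <- runif(1)
  expect_identical(before, after)
})

test_that("lognormal noise preserves positivity; gaussian floors are flagged", {
  sim <- simulate_thermal_series(kd = c(`60` = 0.05),
                                 times_min = seq(0, 100, 20),
                                 noise = "lognormal", noise_sd = 1,
                                 seed = 2)
  expect_true(all(sim$residual_pct > 0))
  expect_false(any(sim$floored))
  simg <- simulate_thermal_series(kd = c(`60` = 0.1),
                                  times_min = seq(0, 120, 20),
                                  noise = "gaussian", noise_sd = 5,
                                  seed = 3)
  expect_true(all(simg$residual_pct > 0))
  expect_true(any(simg$floored))  # late points driven below zero
})

test_that("simulator configuration is validated", {
  expect_error(simulate_thermal_series(), "kd")
  expect_error(simulate_thermal_series(kd = c(`50` = 0.01), A = 1), "not both")
  expect_error(simulate_thermal_series(kd = 0.01), "named")
  expect_error(simulate_thermal_series(kd = c(`50` = 0.01),
                                       times_min = c(10, 5)), "increasing")
  expect_error(simulate_thermal_series(kd = c(`50` = 0.01),
                                       noise = "lognormal", noise_sd = 0.1),
               "seed")
  expect_error(simulate_thermal_series(kd = c(`50` = 0.01), noise_sd = -1),
               "noise_sd")
})

test_that("reuse series decline geometrically after the plateau", {
  r <- simulate_reuse_series(2400, plateau_cycles = 5,
                             per_cycle_decline = 0.077, n_cycles = 10)
  expect_equal(r$retention_pct[1:5], rep(100, 5))
  expect_equal(r$retention_pct[10], 100 * (1 - 0.077)^5)
  expect_equal(round(r$retention_pct[10]), 67)
  expect_equal(simulate_reuse_series(10, 3, 0, 6)$retention_pct, rep(100, 6))
  expect_equal(simulate_reuse_series(1, 0, 0.5, 3)$retention_pct,
               c(100, 50, 25))
  expect_error(simulate_reuse_series(1, 0, 1, 3), "per_cycle_decline")
  expect_error(simulate_reuse_series(0, 0, 0.1, 3), "initial")
})

test_that("clotting-time simulation inverts the Soxhlet formula", {
  sim <- simulate_clotting_times(2400, dilutions = 1)
  expect_equal(sim$clotting_time_s, 10)
  expect_equal(sim$su_per_ml, 2400)
  expect_equal(simulate_clotting_times(10, 1)$clotting_time_s, 2400)
  multi <- simulate_clotting_times(1200, dilutions = c(1, 2, 4))
  expect_equal(multi$su_per_ml, rep(1200, 3))
  expect_error(simulate_clotting_times(0), "true_su_per_ml")
})

test_that("noisy clotting times recover the true activity in the median", {
  su <- vapply(1:500, function(s) {
    simulate_clotting_times(2400, 1, noise_sd = 0.02, seed = s)$su_per_ml
  }, numeric(1))
  expect_lt(abs(stats::median(su) - 2400) / 2400, 0.01)
})
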