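icu <- model_preset("icu")

test_that("simulation bands are ordered and collapse when variability vanishes", {
  cov <- standard_patient()
  reg <- regimen(3, 24, 0.5, n_doses = 2)
  sim <- simulate_profile(icu, cov, reg, n_draws = 400, seed = 2)
  expect_true(all(sim$lower95 <= sim$median + 1e-12))
  expect_true(all(sim$median <= sim$upper95 + 1e-12))
  expect_true(all(sim$lower95 >= 0))

  frozen <- population_model(
    param_spec("CLm", 0.277, 0, "Fixed"),
    param_spec("fr", 0.899, 0, "FPB"),
    param_spec("Vd", 0.335, 0, "FPB"))
  sim0 <- simulate_profile(frozen, cov, reg, n_draws = 50, seed = 1)
  ind <- individual_parameters(c(0.277, 0.899, 0.335), cov)
  det <- concentration(ind, gentapk:::regimen_doses(reg, cov$weight), sim0$time)
  expect_equal(sim0$median, det, tolerance = 1e-12)
  expect_equal(sim0$lower95, sim0$upper95, tolerance = 1e-12)

  one <- simulate_profile(icu, cov, reg, n_draws = 1, seed = 9)
  expect_equal(one$lower95, one$median, tolerance = 1e-12)
  expect_equal(one$upper95, one$median, tolerance = 1e-12)
})

test_that("Monte-Carlo median peak approaches the population-median profile", {
  cov <- standard_patient()
  reg <- regimen(3, 24, 0.5, n_doses = 1)
  t_peak <- 0.5
  sim <- simulate_profile(icu, cov, reg, n_draws = 20000, seed = 5,
                          grid = c(t_peak, 1, 4.5))
  prior <- gentapk:::model_log_prior(icu)
  ind <- individual_parameters(exp(prior$mu), cov)
  det <- concentration(ind, gentapk:::regimen_doses(reg, cov$weight),
                       c(t_peak, 1, 4.5))
  expect_equal(sim$median[1], det[1], tolerance = 0.02)
})

test_that("a forecast with no observations reproduces the a-priori simulation", {
  cov <- standard_patient()
  reg <- regimen(3, 24, 0.5, n_doses = 2)
  doses <- gentapk:::regimen_doses(reg, cov$weight)
  rec <- course_record("F0", cov, doses)
  grid <- seq(0, 48, by = 0.5)
  sim <- simulate_profile(icu, cov, reg, n_draws = 300, seed = 21, grid = grid)
  fc <- bayesian_forecast(icu, rec, n_draws = 300, seed = 21, grid = grid)
  expect_equal(fc$median, sim$median, tolerance = 1e-12)
  expect_equal(fc$lower95, sim$lower95, tolerance = 1e-12)
  expect_equal(fc$upper95, sim$upper95, tolerance = 1e-12)
})

test_that("many noise-free observations pin the posterior median to the true profile", {
  cov <- standard_patient()
  truth <- c(0.277, 0.8, 0.30)
  doses <- dose_events(c(0, 24), round(3 * cov$weight), 0.5)
  t_obs <- seq(0.75, 46, length.out = 20)
  rec <- noise_free_course(truth, cov, doses, t_obs, id = "F20")
  grid <- seq(0.5, 47.5, by = 1)
  fc <- bayesian_forecast(icu, rec, n_draws = 2000, seed = 3, grid = grid)
  ind <- individual_parameters(truth, cov)
  true_profile <- concentration(ind, doses, grid)
  keep <- true_profile > 0.5
  # the MAP retains a slight prior pull even with 20 noise-free samples
  expect_lt(max(abs(fc$median[keep] - true_profile[keep]) / true_profile[keep]),
            0.02)
})

test_that("forecast bands contract as observations accumulate", {
  cov <- standard_patient()
  truth <- c(0.277, 0.8, 0.30)
  doses <- dose_events(0, round(3 * cov$weight), 0.5)
  t_all <- c(1, 4.5, 8, 12)
  grid <- seq(0.5, 24, by = 0.5)
  width <- vapply(c(1, 2, 4), function(nobs) {
    rec <- noise_free_course(truth, cov, doses, t_all[seq_len(nobs)],
                             id = sprintf("W%d", nobs))
    fc <- bayesian_forecast(icu, rec, n_draws = 4000, seed = 13, grid = grid)
    mean(fc$upper95 - fc$lower95)
  }, 0)
  expect_true(all(diff(width) < 0.05))
})

test_that("dose recommendation reproduces the hand-computed scaling and closure", {
  ind <- list(CL = 5, V = 20)
  reg1 <- regimen(120 / 76.2, 24, 0.5, n_doses = 1)
  rec <- recommend_dose(ind, reg1, target_window(9, 12, 0.5), weight = 76.2,
                        target_peak = 10)
  expect_equal(rec$dose, 120 * 10 / concentration(ind, dose_events(0, 120, 0.5), 0.5),
               tolerance = 1e-6)
  expect_equal(rec$dose, 212.8, tolerance = 1e-3)
  # linearity closure: the recommended dose hits the target peak
  expect_equal(rec$predicted_peak, 10, tolerance = 5e-3)
  peak_check <- concentration(ind, dose_events(0, rec$dose, 0.5), 0.5)
  expect_equal(peak_check, 10, tolerance = 5e-3)
  # doubling the target doubles the dose exactly
  rec2 <- recommend_dose(ind, reg1, target_window(9, 12, 0.5), weight = 76.2,
                         target_peak = 20)
  expect_equal(rec2$dose, 2 * rec$dose, tolerance = 1e-12)
})

test_that("an enormous volume forces trough ~ peak and flags the interval", {
  ind <- list(CL = 5, V = 50000)
  rec <- recommend_dose(ind, regimen(3, 24, 0.5, n_doses = 10),
                        target_window(9, 12, 0.5), weight = 76.2)
  expect_gt(rec$predicted_trough / rec$predicted_peak, 0.99)
  expect_false(rec$interval_ok)
})
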