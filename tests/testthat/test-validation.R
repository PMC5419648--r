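endo <- model_preset("endocarditis")

test_that("prediction errors match the defining formula", {
  pairs <- data.frame(c_observed = c(10, 10, 10), c_predicted = c(11, 10, 5))
  expect_equal(prediction_errors(pairs), c(10, 0, -50))
  expect_error(prediction_errors(data.frame(c_observed = 0, c_predicted = 1)),
               "non-positive")
})

test_that("MDPE and MDAPE follow the median conventions", {
  expect_equal(mdpe(c(10, -10, 0)), 0)
  expect_equal(mdape(c(10, -10, 0)), 10)
  # even n: midpoint of the two central order statistics
  expect_equal(mdpe(c(-5, -1, 3, 7)), 1)
  expect_equal(mdape(c(-5, -1, 3, 7)), 4)
  expect_equal(mdpe(rep(-3.2, 5)), -3.2)
  expect_equal(mdape(rep(-3.2, 5)), 3.2)
  expect_error(mdpe(numeric(0)), "empty")
  expect_error(mdape(numeric(0)), "empty")
})

test_that("mdape(pe) equals mdpe(|pe|) for arbitrary error lists", {
  set.seed(5)
  for (i in 1:10) {
    pe <- rnorm(sample(1:40, 1), sd = 20)
    expect_identical(mdape(pe), mdpe(abs(pe)))
  }
})

test_that("prediction errors are invariant to rescaling both axes", {
  set.seed(8)
  pairs <- data.frame(c_observed = runif(20, 1, 15),
                      c_predicted = runif(20, 1, 15))
  pe <- prediction_errors(pairs)
  scaled <- data.frame(c_observed = 3.7 * pairs$c_observed,
                       c_predicted = 3.7 * pairs$c_predicted)
  expect_equal(prediction_errors(scaled), pe, tolerance = 1e-12)
})

test_that("a noise-free cohort at the population medians is predicted exactly in both modes", {
  prior <- gentapk:::model_log_prior(endo)
  rec <- noise_free_course(exp(prior$mu), t_obs = c(1, 4.5, 25))
  for (mode in c("posterior", "a_priori")) {
    pairs <- predict_cohort(list(rec), endo, mode)
    expect_equal(pairs$c_predicted, pairs$c_observed, tolerance = 1e-6)
  }
})

test_that("a-priori predictions ignore the observed values", {
  g <- small_cohort(n = 4, seed = 41)
  p1 <- predict_cohort(g$cohort, endo, "a_priori")
  perturbed <- lapply(g$cohort, function(r) {
    r$observations$conc <- r$observations$conc * 1.5
    r
  })
  p2 <- predict_cohort(perturbed, endo, "a_priori")
  expect_equal(p2$c_predicted, p1$c_predicted, tolerance = 1e-12)
})

test_that("posterior-mode predictions never have higher WSS than a-priori", {
  g <- small_cohort(n = 12, seed = 43, samples_per_course = 4)
  st <- fit_settings()
  for (rec in g$cohort) {
    post <- map_fit(rec, endo, st)
    prior <- gentapk:::model_log_prior(endo)
    th0 <- prior$fixed_value
    th0[prior$est] <- exp(prior$mu[prior$est])
    ind0 <- individual_parameters(th0, rec$covariates,
                                  at_time = rec$doses$start_time[1])
    cpred0 <- concentration(ind0, rec$doses, rec$observations$time)
    sdj <- assay_sd(rec$observations$conc)
    wss0 <- sum(((cpred0 - rec$observations$conc) / sdj)^2)
    expect_lte(post$wss_concentrations + post$wss_parameters, wss0 + 1e-8)
  }
})

test_that("bootstrap CIs are deterministic, ordered and degenerate for constant errors", {
  ci <- bootstrap_validation(rep(4.2, 25), reps = 50, seed = 3)
  expect_equal(ci$ci_mdpe, c(4.2, 4.2))
  expect_equal(ci$ci_mdape, c(4.2, 4.2))
  pe <- rnorm(30, -2, 5)
  c1 <- bootstrap_validation(pe, reps = 500, seed = 11)
  c2 <- bootstrap_validation(pe, reps = 500, seed = 11)
  expect_identical(c1, c2)
  expect_lt(c1$ci_mdpe[1], c1$ci_mdpe[2])
  expect_lte(c1$ci_mdape[1], c1$ci_mdape[2])
  # by-course resampling needs the membership vector
  expect_error(bootstrap_validation(pe, reps = 10, seed = 1, unit = "course"),
               "course_id")
  c3 <- bootstrap_validation(pe, reps = 200, seed = 2, unit = "course",
                             course_id = rep(1:6, each = 5))
  expect_lt(c3$ci_mdpe[1], c3$ci_mdpe[2])
})

test_that("validate_model summarizes a synthetic validation cohort coherently", {
  g <- generate_cohort(validation_cohort_spec(rng_seed = 19))
  vs <- validate_model(g$cohort, endo, reps = 500, seed = 7)
  expect_equal(vs$n_samples, 30)
  expect_equal(vs$n_courses, 14)
  expect_identical(vs$mdpe, mdpe(vs$pe_list))
  expect_identical(vs$mdape, mdape(vs$pe_list))
  expect_true(vs$ci_mdpe[1] <= vs$mdpe && vs$mdpe <= vs$ci_mdpe[2])
  # posterior-mode predictions on a correctly specified cohort are close
  expect_lt(abs(vs$mdpe), 10)
  expect_lt(vs$mdape, 15)
})
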