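test_that("Cockcroft-Gault reproduces hand-computed values and sex ratio", {
  male <- standard_patient()
  female <- patient_covariates(70, "female", 76.2, 174, 86)
  expect_equal(creatinine_clearance(male), 1.23 * 70 * 76.2 / 86,
               tolerance = 1e-12)
  expect_equal(creatinine_clearance(male), 76.29, tolerance = 1e-4)
  expect_equal(creatinine_clearance(female), 64.50, tolerance = 1e-4)
  expect_equal(creatinine_clearance(female) / creatinine_clearance(male),
               1.04 / 1.23, tolerance = 1e-12)
})

test_that("creatinine clearance clamps to zero at age >= 140 with a warning", {
  old <- patient_covariates(140, "male", 76.2, 174, 86)
  expect_warning(clcr <- creatinine_clearance(old), "clamped")
  expect_identical(clcr, 0)
})

test_that("BSA normalization divides by Du Bois surface area", {
  cov <- standard_patient()
  bsa <- 0.007184 * 76.2^0.425 * 174^0.725
  expect_equal(body_surface_area(76.2, 174), bsa, tolerance = 1e-12)
  expect_equal(creatinine_clearance(cov, normalize_bsa = TRUE),
               creatinine_clearance(cov) * 1.73 / bsa, tolerance = 1e-12)
})

test_that("creatinine clearance is monotone decreasing in Scr and age", {
  ages <- seq(20, 135, by = 5)
  clcr_age <- vapply(ages, function(a) {
    creatinine_clearance(patient_covariates(a, "male", 76.2, 174, 86))
  }, 0)
  expect_true(all(diff(clcr_age) < 0))
  scrs <- seq(40, 400, by = 20)
  clcr_scr <- vapply(scrs, function(s) {
    creatinine_clearance(patient_covariates(70, "male", 76.2, 174, s))
  }, 0)
  expect_true(all(diff(clcr_scr) < 0))
})

test_that("time-varying creatinine is piecewise constant (LOCF)", {
  cov <- patient_covariates(70, "male", 76.2, 174,
                            data.frame(time = c(0, 48), scr = c(86, 172)))
  expect_equal(creatinine_clearance(cov, at_time = 47.9),
               creatinine_clearance(standard_patient()))
  expect_equal(creatinine_clearance(cov, at_time = 48),
               creatinine_clearance(standard_patient()) / 2)
  late <- patient_covariates(70, "male", 76.2, 174,
                             data.frame(time = 24, scr = 86))
  expect_error(creatinine_clearance(late, at_time = 0), "incomplete")
})

test_that("corrected lean body mass matches the configured quadratic", {
  cov <- standard_patient()
  lbm <- 1.10 * 76.2 - 128 * (76.2 / 174)^2
  expect_equal(lean_body_mass(cov), lbm, tolerance = 1e-12)
  expect_equal(lean_body_mass(cov), 59.27, tolerance = 1e-3)
  expect_equal(lean_body_mass_corrected(cov), lbm + 0.4 * (76.2 - lbm),
               tolerance = 1e-12)
  expect_equal(lean_body_mass_corrected(cov), 66.04, tolerance = 1e-3)
  # f_fat = 1 degenerates to total body weight
  expect_equal(lean_body_mass_corrected(cov, f_fat = 1), 76.2)
  # very lean: LBM >= W caps at W (needs an extreme weight/height ratio)
  lean <- patient_covariates(30, "male", 40, 230, 80)
  expect_gte(lean_body_mass(lean), 40)
  expect_equal(lean_body_mass_corrected(lean), 40)
  expect_error(lean_body_mass(patient_covariates(70, "female", 120, 100, 86)),
               "implausible")
})

test_that("individual parameters chain the covariate submodels", {
  cov <- standard_patient()
  ind <- individual_parameters(c(0.277, 0.698, 0.312), cov)
  clcr_lh <- creatinine_clearance(cov) * 60 / 1000
  expect_equal(ind$CL, 0.277 * 76.2 / 70 + 0.698 * clcr_lh, tolerance = 1e-12)
  expect_equal(ind$CL, 3.497, tolerance = 1e-3)
  expect_equal(ind$V, 0.312 * lean_body_mass_corrected(cov), tolerance = 1e-12)
  expect_equal(ind$V, 20.60, tolerance = 1e-3)
  expect_equal(ind$k, ind$CL / ind$V, tolerance = 1e-12)
  # linearity: doubling vd doubles V, CL unchanged
  ind2 <- individual_parameters(c(0.277, 0.698, 0.624), cov)
  expect_equal(ind2$V, 2 * ind$V, tolerance = 1e-12)
  expect_equal(ind2$CL, ind$CL)
  # degenerate zero clearance flagged by a non-finite half-life
  ind0 <- individual_parameters(c(0, 0, 0.312), cov)
  expect_equal(ind0$CL, 0)
  expect_false(is.finite(ind0$half_life))
})
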