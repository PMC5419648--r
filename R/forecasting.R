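#' Dosing regimen
#'
#' Weight-based once-daily regimen; the default is the 3 mg/kg, 24 h,
#' 30-minute-infusion scheme used to start gentamicin in endocarditis.
#'
#' @param dose_per_kg mg/kg (default 3)
#' @param interval h between dose starts (default 24)
#' @param infusion_duration h (default 0.5)
#' @param n_doses number of doses
#' @return list of class `regimen`
#' @export
regimen <- function(dose_per_kg = 3, interval = 24, infusion_duration = 0.5,
                    n_doses = 1) {
  stopifnot(dose_per_kg > 0, interval > 0, infusion_duration > 0,
            n_doses >= 1, infusion_duration < interval)
  structure(list(dose_per_kg = dose_per_kg, interval = interval,
                 infusion_duration = infusion_duration, n_doses = n_doses),
            class = "regimen")
}

# Dose events for a regimen applied to a patient (dose rounded to 1 mg).
regimen_doses <- function(reg, weight) {
  dose_mg <- round(reg$dose_per_kg * weight)
  dose_events(start_time = (seq_len(reg$n_doses) - 1) * reg$interval,
              amount = dose_mg, infusion_duration = reg$infusion_duration)
}

#' Therapeutic target window for once-daily dosing
#'
#' @param peak_low,peak_high target peak range, mg/L (default 9-12)
#' @param trough_high maximum acceptable trough, mg/L (default 0.5,
#'   configurable up to 1)
#' @return list of class `target_window`
#' @export
target_window <- function(peak_low = 9, peak_high = 12, trough_high = 0.5) {
  stopifnot(peak_low < peak_high, trough_high < peak_low)
  structure(list(peak_low = peak_low, peak_high = peak_high,
                 trough_high = trough_high), class = "target_window")
}

# Draw n parameter triples (columns CLm, fr, Vd) from the model's log-normal
# population distributions; Fixed or zero-SD parameters are held constant.
# Consumes exactly 3 rnorm streams in a fixed order so that forecasts with
# identical (mu, omega) reproduce prior simulations draw for draw.
draw_parameters <- function(mu, omega, n) {
  m <- matrix(0, n, 3, dimnames = list(NULL, c("CLm", "fr", "Vd")))
  for (p in 1:3) {
    m[, p] <- if (omega[p] > 0) stats::rlnorm(n, mu[p], omega[p]) else
      exp(mu[p])
  }
  m
}

summarize_draws <- function(conc, grid, n_draws, seed) {
  q <- apply(conc, 2, stats::quantile, probs = c(0.025, 0.5, 0.975),
             names = FALSE)
  structure(
    data.frame(time = grid, median = q[2, ], lower95 = q[1, ],
               upper95 = q[3, ]),
    n_draws = n_draws, seed = seed,
    class = c("simulation_summary", "data.frame")
  )
}

#' Monte-Carlo simulation of a concentration-time profile
#'
#' Draws parameter triples from the model's log-normal population
#' distributions (Fixed parameters held constant), maps each through the
#' covariate submodels and the one-compartment model, and summarizes the
#' pointwise median and 2.5/97.5 percentiles. By default the band reflects
#' between-patient parameter variability only; `include_residual` adds
#' assay-error noise to each simulated concentration.
#'
#' @param model a [population_model()]
#' @param cov a [patient_covariates()]
#' @param reg a [regimen()]
#' @param n_draws Monte-Carlo draws (default 5000)
#' @param seed RNG seed
#' @param grid evaluation times, h (default: 0.1 h steps over the regimen
#'   plus one interval)
#' @param include_residual add assay-error noise to the band?
#' @return a `simulation_summary` data.frame: `time`, `median`, `lower95`,
#'   `upper95` (mg/L), with `n_draws` and `seed` attributes
#' @export
simulate_profile <- function(model, cov, reg = regimen(), n_draws = 5000,
                             seed = 1, grid = NULL,
                             include_residual = FALSE) {
  stopifnot(n_draws >= 1)
  prior <- model_log_prior(model)
  if (is.null(grid)) {
    grid <- seq(0, reg$interval * reg$n_doses, by = 0.1)
  }
  doses <- regimen_doses(reg, cov$weight)
  conc <- with_seed(seed, {
    th <- draw_parameters(prior$mu, sqrt(prior$omega2), n_draws)
    cl <- th[, 1] * (cov$weight / 70) +
      th[, 2] * creatinine_clearance(cov, doses$start_time[1]) * 60 / 1000
    v <- th[, 3] * lean_body_mass_corrected(cov)
    m <- conc_one_cmt(cl, v, doses, grid)
    if (n_draws == 1) m <- matrix(m, nrow = 1)
    if (include_residual) {
      m <- m + stats::rnorm(length(m), 0,
                            assay_sd(as.vector(m), model$assay_error_coeffs))
      m[m < 0] <- 0
    }
    m
  })
  summarize_draws(conc, grid, n_draws, seed)
}

#' Bayesian forecast after measured levels
#'
#' MAP-fits the course against the model, then draws parameters from the
#' log-normal Laplace approximation of the posterior (MAP estimate as
#' log-location, curvature-based log-SDs) and summarizes the forecast band.
#' With zero observations the posterior equals the prior and the forecast
#' reproduces [simulate_profile()] draw for draw at the same seed. With
#' informative samples the band contracts inside the a-priori band.
#'
#' @param model a [population_model()]
#' @param record a [course_record()] (its doses are simulated; its
#'   observations drive the posterior)
#' @param future_regimen optional [regimen()] appended one interval after
#'   the last recorded dose
#' @param n_draws Monte-Carlo draws (default 5000)
#' @param seed RNG seed
#' @param grid evaluation times, h
#' @param settings a [fit_settings()]
#' @return a `simulation_summary` data.frame (see [simulate_profile()]) with
#'   the `individual_fit` attached as attribute `fit`
#' @export
bayesian_forecast <- function(model, record, future_regimen = NULL,
                              n_draws = 5000, seed = 1, grid = NULL,
                              settings = fit_settings()) {
  stopifnot(n_draws >= 1)
  fit <- map_fit(record, model, settings)
  doses <- record$doses
  if (!is.null(future_regimen)) {
    t_next <- doses$start_time[nrow(doses)] + future_regimen$interval
    fd <- regimen_doses(future_regimen, record$covariates$weight)
    fd$start_time <- fd$start_time + t_next
    doses <- dose_events(c(doses$start_time, fd$start_time),
                         c(doses$amount, fd$amount),
                         c(doses$infusion_duration, fd$infusion_duration))
  }
  if (is.null(grid)) {
    grid <- seq(0, max(doses$start_time) + 24, by = 0.1)
  }
  cov <- record$covariates
  mu_post <- log(fit$theta)
  omega_post <- fit$estimate$log_posterior_sd
  conc <- with_seed(seed, {
    th <- draw_parameters(mu_post, omega_post, n_draws)
    cl <- th[, 1] * (cov$weight / 70) +
      th[, 2] * creatinine_clearance(cov, doses$start_time[1]) * 60 / 1000
    v <- th[, 3] * lean_body_mass_corrected(cov)
    m <- conc_one_cmt(cl, v, doses, grid)
    if (n_draws == 1) m <- matrix(m, nrow = 1)
    m
  })
  out <- summarize_draws(conc, grid, n_draws, seed)
  attr(out, "fit") <- fit
  out
}

# Steady-state peak (end of infusion) and trough (just before the next
# dose) for a constant regimen, from the closed-form accumulation factor.
steady_state_peak_trough <- function(CL, V, dose_mg, interval, t_inf,
                                     n_doses = Inf) {
  k <- CL / V
  R <- dose_mg / t_inf
  acc <- if (is.finite(n_doses)) {
    (1 - exp(-n_doses * k * interval)) / (1 - exp(-k * interval))
  } else {
    1 / (1 - exp(-k * interval))
  }
  acc <- if (n_doses == 1) 1 else acc
  peak <- (R / CL) * (1 - exp(-k * t_inf)) * acc
  trough <- peak * exp(-k * (interval - t_inf))
  c(peak = peak, trough = trough)
}

#' Dose recommendation for a peak/trough target window
#'
#' Exploits dose-linearity of the one-compartment model: the dose that hits
#' the midpoint of the peak target window is
#' `dose = reference_dose * target_peak / peak_at_reference`, with the peak
#' operationalized as the end-of-infusion concentration at steady state
#' (single dose when `n_doses = 1`). The predicted trough at the given
#' interval is checked against the window; `interval_ok = FALSE` flags that
#' a longer interval is needed.
#'
#' @param ind an [individual_parameters()] estimate (fields `CL`, `V`)
#' @param reg a [regimen()] template providing the reference dose per kg,
#'   interval, infusion duration and number of doses
#' @param window a [target_window()]
#' @param weight patient weight, kg (to convert the template's mg/kg
#'   reference into mg)
#' @param target_peak target peak, mg/L (default: midpoint of the window)
#' @return list with `dose` (mg, exact), `dose_rounded` (mg),
#'   `predicted_peak`, `predicted_trough` (mg/L at the recommended dose) and
#'   `interval_ok`
#' @export
recommend_dose <- function(ind, reg = regimen(), window = target_window(),
                           weight = 70,
                           target_peak = (window$peak_low + window$peak_high) / 2) {
  ref_dose <- reg$dose_per_kg * weight
  pt_ref <- steady_state_peak_trough(ind$CL, ind$V, ref_dose, reg$interval,
                                     reg$infusion_duration, reg$n_doses)
  if (!is.finite(pt_ref["peak"]) || pt_ref["peak"] <= 0) {
    stop("non-positive predicted peak: cannot scale the dose")
  }
  dose <- ref_dose * target_peak / pt_ref[["peak"]]
  pt <- steady_state_peak_trough(ind$CL, ind$V, dose, reg$interval,
                                 reg$infusion_duration, reg$n_doses)
  list(dose = dose, dose_rounded = round(dose),
       predicted_peak = pt[["peak"]], predicted_trough = pt[["trough"]],
       interval_ok = pt[["trough"]] <= window$trough_high)
}
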