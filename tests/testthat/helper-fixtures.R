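# Shared fixtures, built in code at test time.

# The reference adult used throughout: male, 70 y, 76.2 kg, 174 cm, serum
# creatinine 86 umol/L.
standard_patient <- function() {
  patient_covariates(70, "male", 76.2, 174, 86)
}

# A course with known individual parameters and noise-free observations
# generated from the model itself (for closure and optimality checks).
noise_free_course <- function(theta, cov = standard_patient(),
                              doses = dose_events(c(0, 24), 3 * 76.2, 0.5),
                              t_obs = c(1, 4.5, 25, 28.5),
                              id = "NF1") {
  ind <- individual_parameters(theta, cov, at_time = doses$start_time[1])
  course_record(id, cov, doses, pk_observations(t_obs, concentration(ind, doses, t_obs)))
}

# Random dosing regimens + parameters for property checks, drawn inside
# clinically plausible ranges.
random_pk_case <- function() {
  cl <- runif(1, 0.5, 12)
  v <- runif(1, 8, 40)
  n_doses <- sample(1:5, 1)
  interval <- runif(1, 8, 36)
  dur <- runif(1, 0.25, 2)
  doses <- dose_events((seq_len(n_doses) - 1) * interval,
                       runif(1, 40, 400), dur)
  list(CL = cl, V = v, doses = doses,
       times = sort(runif(8, 0, n_doses * interval + 12)))
}

# Small synthetic cohort for fast estimation tests.
small_cohort <- function(n = 8, seed = 11, samples_per_course = 3,
                         noise = TRUE) {
  generate_cohort(cohort_spec(n_courses = n,
                              target_total_samples = n * samples_per_course,
                              noise = noise, rng_seed = seed))
}
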