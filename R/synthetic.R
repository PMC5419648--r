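#' Specification of a synthetic cohort
#'
#' Defaults emulate the modeling cohort of an adult endocarditis treatment
#' setting: 65 courses contributing 221 samples in total, demographics drawn
#' as truncated normals inside the observed ranges (age mean 69.3 y, range
#' 32-92; weight 76.2 kg, 46-121; height 173.9 cm, 149-193; about one female
#' to two males), creatinine chosen to induce a creatinine-clearance range
#' of 8.7-157.5 ml/min, 3 mg/kg once-daily 30-minute infusions (2-7 doses),
#' and a fixed-count sampling scheme of a 0.5 h post-infusion peak plus a
#' mid-interval sample, mirroring a t = 1 h / t = 4.5 h design. True
#' parameters are drawn log-normally from `truth_model`; observation noise
#' follows the assay-error polynomial.
#'
#' @param n_courses number of courses (default 65)
#' @param target_total_samples total observations, allocated
#'   deterministically across courses so the count is exact (default 221)
#' @param truth_model generating [population_model()] (default the
#'   endocarditis preset)
#' @param age_mean,age_range,weight_mean,weight_range,height_mean,height_range
#'   demographic truncated-normal means and ranges; SDs are range width / 4
#' @param p_female probability of female sex (default 1/3)
#' @param clcr_range induced creatinine-clearance range, ml/min
#' @param reg dosing [regimen()] template (dose count drawn per course from
#'   `n_doses_range`)
#' @param n_doses_range inclusive range of doses per course
#' @param sample_offsets sampling times (h) after the start of a sampled
#'   dose: peak then mid-interval
#' @param noise add assay-error observation noise? (`FALSE` gives exact
#'   model concentrations)
#' @param loq lower limit of quantification, mg/L; noisy observations are
#'   truncated below at LOQ
#' @param rng_seed seed for [generate_cohort()]
#' @return list of class `cohort_spec`
#' @export
cohort_spec <- function(n_courses = 65, target_total_samples = 221,
                        truth_model = model_preset("endocarditis"),
                        age_mean = 69.3, age_range = c(32, 92),
                        weight_mean = 76.2, weight_range = c(46, 121),
                        height_mean = 173.9, height_range = c(149, 193),
                        p_female = 1 / 3,
                        clcr_range = c(8.7, 157.5),
                        reg = regimen(3, 24, 0.5, n_doses = 1),
                        n_doses_range = c(2, 7),
                        sample_offsets = c(1.0, 4.5),
                        noise = TRUE, loq = 0.2, rng_seed = 1) {
  stopifnot(n_courses >= 1, target_total_samples >= n_courses)
  structure(as.list(environment()), class = "cohort_spec")
}

#' Validation-cohort variant of [cohort_spec()]
#'
#' 14 courses with 30 samples and the validation cohort's demographic
#' ranges (age 63.4 y, 30-88; weight 80.3 kg, 65-90; height 177.7 cm,
#' 169-195; creatinine clearance 28.4-181.5 ml/min).
#'
#' @param ... overrides passed to [cohort_spec()]
#' @return list of class `cohort_spec`
#' @export
validation_cohort_spec <- function(...) {
  defaults <- list(n_courses = 14, target_total_samples = 30,
                   age_mean = 63.4, age_range = c(30, 88),
                   weight_mean = 80.3, weight_range = c(65, 90),
                   height_mean = 177.7, height_range = c(169, 195),
                   clcr_range = c(28.4, 181.5))
  args <- utils::modifyList(defaults, list(...))
  do.call(cohort_spec, args)
}

# Deterministic per-course sample counts: floor(total/n) each, the
# remainder getting one extra, so the cohort total is hit exactly.
allocate_samples <- function(n_courses, total) {
  base <- total %/% n_courses
  extra <- total - base * n_courses
  counts <- rep(base, n_courses)
  if (extra > 0) counts[seq_len(extra)] <- counts[seq_len(extra)] + 1L
  counts
}

#' Generate a synthetic cohort with a hidden truth table
#'
#' Per course: demographics are drawn as truncated normals inside the
#' spec's ranges; a target creatinine clearance is drawn uniformly in
#' `clcr_range` and inverted through Cockcroft-Gault to a (single, time-0)
#' serum creatinine; true `(CLm, fr, Vd)` are drawn log-normally from the
#' truth model (Fixed / zero-SD parameters held constant); concentrations
#' are simulated at the fixed-count sampling scheme and observation noise
#' `N(0, assay_sd(c_true))` is added, truncated below at LOQ.
#'
#' @param spec a [cohort_spec()]
#' @param seed overrides `spec$rng_seed`
#' @return list with `cohort` (list of [course_record()]) and `truth`
#'   (data.frame of per-course true parameters `clm`, `fr`, `vd`, `CL`,
#'   `V`, `k`), plus the generating model as attribute `truth_model`
#' @export
generate_cohort <- function(spec, seed = spec$rng_seed) {
  stopifnot(inherits(spec, "cohort_spec"))
  counts <- allocate_samples(spec$n_courses, spec$target_total_samples)
  if (any(counts < 1)) stop("spec yields fewer than one observation per course")
  prior <- model_log_prior(spec$truth_model)

  with_seed(seed, {
    n <- spec$n_courses
    sex <- ifelse(stats::runif(n) < spec$p_female, "female", "male")
    age <- rtruncnorm(n, spec$age_mean, diff(spec$age_range) / 4,
                      spec$age_range[1], spec$age_range[2])
    weight <- rtruncnorm(n, spec$weight_mean, diff(spec$weight_range) / 4,
                         spec$weight_range[1], spec$weight_range[2])
    height <- rtruncnorm(n, spec$height_mean, diff(spec$height_range) / 4,
                         spec$height_range[1], spec$height_range[2])
    clcr_target <- stats::runif(n, spec$clcr_range[1], spec$clcr_range[2])
    n_doses <- sample(seq(spec$n_doses_range[1], spec$n_doses_range[2]),
                      n, replace = TRUE)
    theta <- draw_parameters(prior$mu, sqrt(prior$omega2), n)

    cohort <- vector("list", n)
    truth <- vector("list", n)
    for (i in seq_len(n)) {
      f <- if (sex[i] == "male") 1.23 else 1.04
      scr <- f * (140 - age[i]) * weight[i] / clcr_target[i]
      cov <- patient_covariates(age[i], sex[i], weight[i], height[i], scr)
      reg_i <- regimen(spec$reg$dose_per_kg, spec$reg$interval,
                       spec$reg$infusion_duration, n_doses[i])
      doses <- regimen_doses(reg_i, weight[i])

      s <- counts[i]
      occ <- (seq_len(s) - 1) %/% length(spec$sample_offsets) + 1
      n_occ <- max(occ)
      dose_idx <- round(seq(1, n_doses[i], length.out = n_occ))
      off <- spec$sample_offsets[(seq_len(s) - 1) %% length(spec$sample_offsets) + 1]
      t_obs <- doses$start_time[dose_idx[occ]] + off

      ind <- individual_parameters(theta[i, ], cov,
                                   at_time = doses$start_time[1])
      c_true <- concentration(ind, doses, t_obs)
      c_obs <- if (spec$noise) {
        pmax(c_true + stats::rnorm(s, 0, assay_sd(c_true,
               spec$truth_model$assay_error_coeffs)), spec$loq)
      } else {
        c_true
      }
      id <- sprintf("C%03d", i)
      cohort[[i]] <- course_record(id, cov, doses,
                                   pk_observations(t_obs, c_obs, spec$loq))
      truth[[i]] <- data.frame(course_id = id, clm = theta[i, 1],
                               fr = theta[i, 2], vd = theta[i, 3],
                               CL = ind$CL, V = ind$V, k = ind$k)
    }
    truth <- do.call(rbind, truth)
    attr(truth, "truth_model") <- spec$truth_model
    list(cohort = cohort, truth = truth)
  })
}

#' Parameter-recovery report against the generating truth
#'
#' Compares a converged population fit with the cohort's hidden truth:
#' per-parameter population bias
#' `(estimated population mean - truth mean) / truth mean` and the RMSE of
#' the individual estimates against the true per-course values.
#'
#' @param cohort the generated cohort
#' @param truth the truth table from [generate_cohort()]
#' @param fit a `population_fit` from [itsb_fit()]
#' @return data.frame with columns `parameter`, `truth_mean`,
#'   `estimated_mean`, `bias`, `rmse_individual`
#' @export
truth_recovery_report <- function(cohort, truth, fit) {
  stopifnot(inherits(fit, "population_fit"))
  fit_ids <- vapply(fit$fits, `[[`, "", "course_id")
  if (!setequal(fit_ids, truth$course_id) ||
      !setequal(vapply(cohort, `[[`, "", "course_id"), truth$course_id)) {
    stop("course ids of cohort, truth table and fit do not match")
  }
  tm <- attr(truth, "truth_model")
  truth <- truth[match(fit_ids, truth$course_id), ]
  truth_means <- if (!is.null(tm)) {
    tab <- model_param_table(tm)
    tab$mean
  } else {
    c(mean(truth$clm), mean(truth$fr), mean(truth$vd))
  }
  est_tab <- model_param_table(fit$model)
  est_ind <- t(vapply(fit$fits, `[[`, numeric(3), "theta"))
  true_ind <- as.matrix(truth[, c("clm", "fr", "vd")])
  data.frame(
    parameter = c("CLm", "fr", "Vd"),
    truth_mean = truth_means,
    estimated_mean = est_tab$mean,
    bias = (est_tab$mean - truth_means) / truth_means,
    rmse_individual = sqrt(colMeans((est_ind - true_ind)^2))
  )
}
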