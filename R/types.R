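#' Patient covariates for a treatment course
#'
#' Demographics and the serum-creatinine series needed by the covariate
#' submodels. Creatinine is handled as piecewise-constant in time (last
#' observation carried forward).
#'
#' @param age age in years (>= 18)
#' @param sex `"male"` or `"female"`
#' @param weight total body weight in kg
#' @param height height in cm
#' @param creatinine serum creatinine in umol/L: either a single value
#'   (taken to hold from time 0) or a data.frame with columns `time` (h,
#'   strictly increasing) and `scr` (umol/L)
#' @return an object of class `patient_covariates`
#' @export
patient_covariates <- function(age, sex, weight, height, creatinine) {
  sex <- match.arg(sex, c("male", "female"))
  if (is.numeric(creatinine) && is.null(dim(creatinine))) {
    creatinine <- data.frame(time = 0, scr = creatinine)
  }
  stopifnot(
    is.data.frame(creatinine),
    all(c("time", "scr") %in% names(creatinine)),
    nrow(creatinine) >= 1
  )
  creatinine <- creatinine[order(creatinine$time), c("time", "scr")]
  if (age < 18) stop("age must be >= 18 years (adult cohort)")
  if (weight <= 0 || height <= 0) stop("weight and height must be positive")
  if (any(creatinine$scr <= 0)) stop("serum creatinine values must be positive")
  if (any(diff(creatinine$time) <= 0)) {
    stop("creatinine series times must be strictly increasing")
  }
  structure(
    list(age = age, sex = sex, weight = weight, height = height,
         creatinine = creatinine),
    class = "patient_covariates"
  )
}

#' Dose events table
#'
#' @param start_time infusion start times (h, >= 0)
#' @param amount dose amounts (mg, > 0)
#' @param infusion_duration infusion durations (h, > 0); recycled
#' @return data.frame of class `dose_events` with an `infusion_rate` column
#'   (mg/h)
#' @export
dose_events <- function(start_time, amount, infusion_duration = 0.5) {
  d <- data.frame(start_time = start_time, amount = amount,
                  infusion_duration = infusion_duration)
  if (nrow(d) < 1) stop("at least one dose event is required")
  if (any(d$amount <= 0)) stop("dose amounts must be positive")
  if (any(d$infusion_duration <= 0)) stop("infusion durations must be positive")
  if (any(d$start_time < 0)) stop("dose start times must be >= 0")
  d$infusion_rate <- d$amount / d$infusion_duration
  d <- d[order(d$start_time), ]
  rownames(d) <- NULL
  class(d) <- c("dose_events", "data.frame")
  d
}

#' Timed concentration observations
#'
#' Observations below the lower limit of quantification (LOQ, 0.2 mg/L for
#' the EMIT assay) are flagged rather than rejected; the fitting policy
#' decides whether they are excluded or retained at LOQ/2.
#'
#' @param time sampling times (h, >= 0)
#' @param conc measured concentrations (mg/L, >= 0)
#' @param loq lower limit of quantification (mg/L)
#' @return data.frame of class `pk_observations` with a `below_loq` flag
#' @export
pk_observations <- function(time, conc, loq = 0.2) {
  o <- data.frame(time = time, conc = conc)
  if (any(o$time < 0)) stop("observation times must be >= 0")
  if (any(o$conc < 0)) stop("concentrations must be >= 0")
  o$below_loq <- o$conc < loq
  o <- o[order(o$time), ]
  rownames(o) <- NULL
  class(o) <- c("pk_observations", "data.frame")
  o
}

#' One treatment course: covariates, doses and observations
#'
#' A patient contributing several treatment episodes appears as several
#' courses with distinct ids.
#'
#' @param course_id opaque identifier
#' @param covariates a [patient_covariates()] object
#' @param doses a [dose_events()] table (>= 1 row)
#' @param observations a [pk_observations()] table (may be empty)
#' @return an object of class `course_record`
#' @export
course_record <- function(course_id, covariates, doses,
                          observations = pk_observations(numeric(0), numeric(0))) {
  stopifnot(inherits(covariates, "patient_covariates"),
            inherits(doses, "dose_events"),
            inherits(observations, "pk_observations"))
  structure(
    list(course_id = as.character(course_id), covariates = covariates,
         doses = doses, observations = observations),
    class = "course_record"
  )
}

#' @export
print.course_record <- function(x, ...) {
  cat(sprintf("<course %s: %s, %g y, %g kg; %d doses, %d observations>\n",
              x$course_id, x$covariates$sex, x$covariates$age,
              x$covariates$weight, nrow(x$doses), nrow(x$observations)))
  invisible(x)
}

#' Specification of one population parameter
#'
#' Each parameter carries its arithmetic population mean and SD and an
#' estimation setting: `"Bayesian"` (individual estimation with a prior whose
#' population values are updated between iterations), `"FPB"` (fixed
#' population Bayesian: individual estimation against a prior whose
#' population values never move), or `"Fixed"` (held at the population value,
#' SD treated as 0).
#'
#' @param name one of `"CLm"`, `"fr"`, `"Vd"`
#' @param mean arithmetic population mean (CLm: L/h per 70 kg BW; fr:
#'   fraction of creatinine clearance; Vd: L/kg corrected lean body mass)
#' @param sd arithmetic population SD (same units)
#' @param setting `"Bayesian"`, `"FPB"` or `"Fixed"`
#' @return an object of class `param_spec`
#' @export
param_spec <- function(name, mean, sd, setting = "Bayesian") {
  name <- match.arg(name, c("CLm", "fr", "Vd"))
  setting <- match.arg(setting, c("Bayesian", "FPB", "Fixed"))
  stopifnot(mean > 0, sd >= 0)
  if (setting == "Fixed") sd <- 0
  structure(list(name = name, mean = mean, sd = sd, setting = setting),
            class = "param_spec")
}

#' Population pharmacokinetic model
#'
#' Bundles the three parameter specifications with the concentration-
#' dependent assay-error polynomial `SD(C) = a0 + a1*C + a2*C^2` used to
#' weight concentration residuals.
#'
#' @param clm,fr,vd [param_spec()] objects for metabolic clearance, renal
#'   fraction and volume of distribution
#' @param assay_error_coeffs polynomial coefficients `(a0, a1, a2)` in mg/L,
#'   dimensionless and (mg/L)^-1
#' @param name optional model label
#' @return an object of class `population_model`
#' @export
population_model <- function(clm, fr, vd,
                             assay_error_coeffs = c(0.0766, 0.0006, 0.0064),
                             name = "custom") {
  stopifnot(inherits(clm, "param_spec"), clm$name == "CLm",
            inherits(fr, "param_spec"), fr$name == "fr",
            inherits(vd, "param_spec"), vd$name == "Vd",
            length(assay_error_coeffs) == 3)
  structure(
    list(clm = clm, fr = fr, vd = vd,
         assay_error_coeffs = as.numeric(assay_error_coeffs), name = name),
    class = "population_model"
  )
}

#' @export
print.population_model <- function(x, ...) {
  cat(sprintf("<population model '%s'>\n", x$name))
  for (p in list(x$clm, x$fr, x$vd)) {
    cat(sprintf("  %-3s %7.3f +/- %.3f  [%s]\n", p$name, p$mean, p$sd, p$setting))
  }
  cat(sprintf("  assay SD = %g + %g C + %g C^2 (mg/L)\n",
              x$assay_error_coeffs[1], x$assay_error_coeffs[2],
              x$assay_error_coeffs[3]))
  invisible(x)
}

# Internal: parameters as a 3-row data.frame for uniform iteration.
model_param_table <- function(model) {
  ps <- list(model$clm, model$fr, model$vd)
  data.frame(
    name = vapply(ps, `[[`, "", "name"),
    mean = vapply(ps, `[[`, 0, "mean"),
    sd = vapply(ps, `[[`, 0, "sd"),
    setting = vapply(ps, `[[`, "", "setting"),
    stringsAsFactors = FALSE
  )
}

# Internal: replace mean/sd of one parameter, preserving its setting.
update_param <- function(spec, mean, sd) {
  param_spec(spec$name, mean, sd, spec$setting)
}

#' Change estimation settings of a population model
#'
#' Convenience for running the settings grid (e.g. CLm
#' Bayesian/FPB/Fixed) without rebuilding the model by hand.
#'
#' @param model a [population_model()]
#' @param clm,fr,vd new settings (or `NULL` to keep)
#' @return the modified model
#' @export
with_settings <- function(model, clm = NULL, fr = NULL, vd = NULL) {
  set1 <- function(spec, s) {
    if (is.null(s)) return(spec)
    param_spec(spec$name, spec$mean, spec$sd, s)
  }
  model$clm <- set1(model$clm, clm)
  model$fr <- set1(model$fr, fr)
  model$vd <- set1(model$vd, vd)
  model
}
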