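#' Write a cohort to the two-file CSV dataset format
#'
#' The dataset is a courses table (`course_id, age_y, sex, weight_kg,
#' height_cm`) and an events table (`course_id, event_type, time_h,
#' amount_mg, infusion_h, conc_mg_per_l, scr_umol_per_l`) with `event_type`
#' one of `dose`, `obs`, `creatinine`. Units are fixed in the column names;
#' numbers are serialized with 15 significant digits so a write/read/write
#' round trip is byte-identical.
#'
#' @param cohort list of [course_record()]
#' @param courses_csv,events_csv output paths
#' @return invisibly, a list with the two paths
#' @export
write_dataset <- function(cohort, courses_csv, events_csv) {
  fmt <- function(x) {
    out <- formatC(x, digits = 15, format = "g")
    out[is.na(x)] <- ""
    out
  }
  courses <- do.call(rbind, lapply(cohort, function(r) {
    data.frame(course_id = r$course_id, age_y = r$covariates$age,
               sex = r$covariates$sex, weight_kg = r$covariates$weight,
               height_cm = r$covariates$height)
  }))
  courses <- courses[order(courses$course_id), ]
  courses$age_y <- fmt(courses$age_y)
  courses$weight_kg <- fmt(courses$weight_kg)
  courses$height_cm <- fmt(courses$height_cm)

  events <- do.call(rbind, lapply(cohort, function(r) {
    rbind(
      data.frame(course_id = r$course_id, event_type = "creatinine",
                 time_h = r$covariates$creatinine$time, amount_mg = NA_real_,
                 infusion_h = NA_real_, conc_mg_per_l = NA_real_,
                 scr_umol_per_l = r$covariates$creatinine$scr),
      data.frame(course_id = r$course_id, event_type = "dose",
                 time_h = r$doses$start_time, amount_mg = r$doses$amount,
                 infusion_h = r$doses$infusion_duration,
                 conc_mg_per_l = NA_real_, scr_umol_per_l = NA_real_),
      if (nrow(r$observations) > 0) {
        data.frame(course_id = r$course_id, event_type = "obs",
                   time_h = r$observations$time, amount_mg = NA_real_,
                   infusion_h = NA_real_,
                   conc_mg_per_l = r$observations$conc,
                   scr_umol_per_l = NA_real_)
      }
    )
  }))
  events <- events[order(events$course_id, events$time_h,
                         match(events$event_type,
                               c("creatinine", "dose", "obs"))), ]
  for (col in c("time_h", "amount_mg", "infusion_h", "conc_mg_per_l",
                "scr_umol_per_l")) {
    events[[col]] <- fmt(events[[col]])
  }
  utils::write.csv(courses, courses_csv, row.names = FALSE, quote = FALSE)
  utils::write.csv(events, events_csv, row.names = FALSE, quote = FALSE)
  invisible(list(courses_csv = courses_csv, events_csv = events_csv))
}

#' Read a cohort from the two-file CSV dataset format
#'
#' Validates the layout documented in [write_dataset()]: required columns
#' must be present (unknown columns are preserved but ignored), every
#' events row must reference an existing course, every course needs at
#' least one dose and one creatinine value, and dose rows need a positive
#' infusion duration. Events are sorted per course on read regardless of
#' file order. Observations below the LOQ are flagged. A parse report
#' (counts of courses, doses, observations, below-LOQ flags) is attached as
#' attribute `report` and shown as a message.
#'
#' @param courses_csv,events_csv input paths
#' @param loq lower limit of quantification used for flagging, mg/L
#' @param quiet suppress the parse-report message?
#' @return list of [course_record()]
#' @export
read_dataset <- function(courses_csv, events_csv, loq = 0.2, quiet = FALSE) {
  for (p in c(courses_csv, events_csv)) {
    if (!file.exists(p)) stop(sprintf("file not found: %s", p))
  }
  courses <- utils::read.csv(courses_csv, stringsAsFactors = FALSE)
  events <- utils::read.csv(events_csv, stringsAsFactors = FALSE)
  need_c <- c("course_id", "age_y", "sex", "weight_kg", "height_cm")
  need_e <- c("course_id", "event_type", "time_h", "amount_mg", "infusion_h",
              "conc_mg_per_l", "scr_umol_per_l")
  miss <- setdiff(need_c, names(courses))
  if (length(miss)) stop(sprintf("courses table missing column(s): %s",
                                 paste(miss, collapse = ", ")))
  miss <- setdiff(need_e, names(events))
  if (length(miss)) stop(sprintf("events table missing column(s): %s",
                                 paste(miss, collapse = ", ")))
  courses$course_id <- as.character(courses$course_id)
  events$course_id <- as.character(events$course_id)
  unknown <- setdiff(unique(events$course_id), courses$course_id)
  if (length(unknown)) {
    stop(sprintf("events reference unknown course(s): %s",
                 paste(unknown, collapse = ", ")))
  }
  bad <- which(events$event_type == "dose" &
                 (is.na(events$infusion_h) | events$infusion_h <= 0))
  if (length(bad)) {
    stop(sprintf("dose row(s) with non-positive infusion duration: event row %s",
                 paste(bad, collapse = ", ")))
  }

  courses <- courses[order(courses$course_id), ]
  out <- vector("list", nrow(courses))
  n_doses <- n_obs <- n_below <- 0L
  for (i in seq_len(nrow(courses))) {
    id <- courses$course_id[i]
    ev <- events[events$course_id == id, ]
    ev <- ev[order(ev$time_h), ]
    crea <- ev[ev$event_type == "creatinine", ]
    dose <- ev[ev$event_type == "dose", ]
    obs <- ev[ev$event_type == "obs", ]
    if (nrow(dose) == 0) {
      stop(sprintf("course %s has no dose event (>= 1 required)", id))
    }
    if (nrow(crea) == 0) {
      stop(sprintf("course %s has no serum creatinine (incomplete record)", id))
    }
    cov <- patient_covariates(courses$age_y[i], courses$sex[i],
                              courses$weight_kg[i], courses$height_cm[i],
                              data.frame(time = crea$time_h,
                                         scr = crea$scr_umol_per_l))
    rec <- course_record(
      id, cov,
      dose_events(dose$time_h, dose$amount_mg, dose$infusion_h),
      pk_observations(obs$time_h, obs$conc_mg_per_l, loq)
    )
    n_doses <- n_doses + nrow(dose)
    n_obs <- n_obs + nrow(obs)
    n_below <- n_below + sum(rec$observations$below_loq)
    out[[i]] <- rec
  }
  report <- list(n_courses = nrow(courses), n_doses = n_doses,
                 n_observations = n_obs, n_below_loq = n_below)
  if (!quiet) {
    message(sprintf(
      "read %d courses: %d doses, %d observations (%d flagged below LOQ %g mg/L)",
      report$n_courses, report$n_doses, report$n_observations,
      report$n_below_loq, loq))
  }
  attr(out, "report") <- report
  out
}

#' Write a population-fit report to JSON
#'
#' Converged model, per-course estimates, goodness of fit and the iteration
#' trace, serialized at full precision; the embedded model round-trips
#' through the preset schema of [read_model_json()].
#'
#' @param fit a `population_fit`
#' @param path output file
#' @return `path`, invisibly
#' @export
write_fit_json <- function(fit, path) {
  stopifnot(inherits(fit, "population_fit"))
  tab <- model_param_table(fit$model)
  j <- list(
    model = list(
      name = fit$model$name,
      parameters = stats::setNames(lapply(1:3, function(i) {
        list(mean = tab$mean[i], sd = tab$sd[i], setting = tab$setting[i])
      }), tab$name),
      assay_error_coeffs = fit$model$assay_error_coeffs
    ),
    goodness_of_fit = list(aic = fit$aic,
                           sum_wss_over_df = fit$sum_wss_over_df,
                           df = fit$df),
    converged = fit$converged,
    iterations_run = fit$iterations_run,
    courses = lapply(fit$fits, function(f) {
      list(course_id = f$course_id,
           theta = as.list(f$theta),
           CL = f$estimate$CL, V = f$estimate$V, k = f$estimate$k,
           wss_concentrations = f$wss_concentrations,
           wss_parameters = f$wss_parameters,
           n_observations_used = f$n_observations_used)
    }),
    iteration_trace = fit$iteration_trace
  )
  jsonlite::write_json(j, path, auto_unbox = TRUE, digits = NA,
                       dataframe = "columns")
  invisible(path)
}
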