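#' Predicted vs observed concentrations for a cohort
#'
#' External-validation predictions of a population model on a cohort, with
#' the population values never updated. Two modes:
#' \describe{
#'   \item{`posterior` (default)}{one MAP cycle per course against the model
#'     (the model's own settings decide which parameters are individually
#'     estimated), then prediction at each observation time from the fitted
#'     parameters — the model's ability to predict an individual patient's
#'     levels from its own samples.}
#'   \item{`a_priori`}{prediction from the population medians with no
#'     fitting; observations play no role.}
#' }
#'
#' @param cohort list of [course_record()], each with >= 1 observation
#' @param model a [population_model()]
#' @param mode `"posterior"` or `"a_priori"`
#' @param settings a [fit_settings()]
#' @return data.frame of class `prediction_pairs` with columns `course_id`,
#'   `time`, `c_observed`, `c_predicted`, `mode`; courses whose fit fails
#'   are excluded with a warning (count in attribute `n_failed`)
#' @export
predict_cohort <- function(cohort, model, mode = c("posterior", "a_priori"),
                           settings = fit_settings()) {
  mode <- match.arg(mode)
  stopifnot(inherits(model, "population_model"))
  prior <- model_log_prior(model)
  out <- vector("list", length(cohort))
  n_failed <- 0L
  for (i in seq_along(cohort)) {
    rec <- cohort[[i]]
    obs <- usable_observations(rec, settings$loq_policy)
    if (nrow(obs) == 0) next
    if (mode == "a_priori") {
      th <- prior$fixed_value
      th[prior$est] <- exp(prior$mu[prior$est])
      ind <- individual_parameters(th, rec$covariates,
                                   at_time = rec$doses$start_time[1])
      cpred <- concentration(ind, rec$doses, obs$time)
    } else {
      fit <- tryCatch(map_fit(rec, model, settings), error = function(e) NULL)
      if (is.null(fit)) {
        n_failed <- n_failed + 1L
        warning(sprintf("course %s excluded: MAP fit failed", rec$course_id))
        next
      }
      cpred <- concentration(fit$estimate, rec$doses, obs$time)
    }
    out[[i]] <- data.frame(course_id = rec$course_id, time = obs$time,
                           c_observed = obs$conc, c_predicted = cpred,
                           mode = mode)
  }
  pairs <- do.call(rbind, out)
  if (is.null(pairs)) pairs <- data.frame(course_id = character(0),
                                          time = numeric(0),
                                          c_observed = numeric(0),
                                          c_predicted = numeric(0),
                                          mode = character(0))
  rownames(pairs) <- NULL
  attr(pairs, "n_failed") <- n_failed
  class(pairs) <- c("prediction_pairs", "data.frame")
  pairs
}

#' Prediction errors (%)
#'
#' `PE_j = 100 * (Cpredicted_j - Cobserved_j) / Cobserved_j`.
#'
#' @param pairs a `prediction_pairs` data.frame (or any data.frame with
#'   `c_observed` and `c_predicted` columns)
#' @return numeric vector of prediction errors in percent
#' @export
prediction_errors <- function(pairs) {
  if (any(pairs$c_observed <= 0)) {
    stop("prediction error undefined for non-positive observed concentration")
  }
  100 * (pairs$c_predicted - pairs$c_observed) / pairs$c_observed
}

#' Median prediction error (bias, %)
#'
#' Sample median of the prediction errors; for even n, the midpoint of the
#' two central order statistics.
#'
#' @param pe numeric vector of prediction errors (%)
#' @return %
#' @export
mdpe <- function(pe) {
  if (length(pe) == 0) stop("empty prediction-error list")
  stats::median(pe)
}

#' Median absolute prediction error (precision, %)
#'
#' Sample median of the absolute prediction errors.
#'
#' @param pe numeric vector of prediction errors (%)
#' @return %
#' @export
mdape <- function(pe) {
  if (length(pe) == 0) stop("empty prediction-error list")
  stats::median(abs(pe))
}

#' Bootstrap confidence intervals for MDPE and MDAPE
#'
#' Nonparametric percentile bootstrap: prediction errors are resampled with
#' replacement (`unit = "sample"`, default) or whole courses are resampled
#' (`unit = "course"`), and the 2.5/97.5 percentiles of the replicate MDPE
#' and MDAPE form the intervals.
#'
#' @param pe numeric vector of prediction errors (%)
#' @param reps bootstrap replicates (default 10000)
#' @param seed RNG seed (deterministic results given the seed)
#' @param unit resampling unit, `"sample"` or `"course"`
#' @param course_id course membership of each error (required for
#'   `unit = "course"`)
#' @return list with `ci_mdpe` and `ci_mdape`, each `c(lo, hi)` in %
#' @export
bootstrap_validation <- function(pe, reps = 10000, seed = 1,
                                 unit = c("sample", "course"),
                                 course_id = NULL) {
  stopifnot(reps >= 1, length(pe) >= 1)
  unit <- match.arg(unit)
  stat <- with_seed(seed, {
    if (unit == "sample") {
      n <- length(pe)
      m <- matrix(pe[sample.int(n, n * reps, replace = TRUE)], nrow = n)
      rbind(apply(m, 2, stats::median), apply(abs(m), 2, stats::median))
    } else {
      if (is.null(course_id)) stop("course_id required for unit = 'course'")
      split_pe <- split(pe, course_id)
      k <- length(split_pe)
      vapply(seq_len(reps), function(r) {
        v <- unlist(split_pe[sample.int(k, k, replace = TRUE)],
                    use.names = FALSE)
        c(stats::median(v), stats::median(abs(v)))
      }, numeric(2))
    }
  })
  list(
    ci_mdpe = unname(stats::quantile(stat[1, ], c(0.025, 0.975))),
    ci_mdape = unname(stats::quantile(stat[2, ], c(0.025, 0.975)))
  )
}

#' External validation summary of a population model
#'
#' Runs [predict_cohort()], computes per-sample prediction errors, MDPE
#' (bias) and MDAPE (precision), and their bootstrap 95% confidence
#' intervals.
#'
#' @param cohort list of [course_record()]
#' @param model a [population_model()]
#' @param mode prediction mode, see [predict_cohort()]
#' @param reps bootstrap replicates (default 10000)
#' @param seed RNG seed
#' @param settings a [fit_settings()]
#' @return an object of class `validation_summary`: `pairs`, `pe_list`,
#'   `mdpe`, `mdape`, `ci_mdpe`, `ci_mdape`, `n_samples`, `n_courses`
#' @export
validate_model <- function(cohort, model, mode = "posterior", reps = 10000,
                           seed = 1, settings = fit_settings()) {
  pairs <- predict_cohort(cohort, model, mode, settings)
  pe <- prediction_errors(pairs)
  ci <- bootstrap_validation(pe, reps = reps, seed = seed)
  structure(
    list(model = model$name, mode = mode, pairs = pairs, pe_list = pe,
         mdpe = mdpe(pe), mdape = mdape(pe),
         ci_mdpe = ci$ci_mdpe, ci_mdape = ci$ci_mdape,
         n_samples = nrow(pairs),
         n_courses = length(unique(pairs$course_id))),
    class = "validation_summary"
  )
}

#' @export
print.validation_summary <- function(x, ...) {
  cat(sprintf("<validation of '%s' model (%s mode): %d samples, %d courses>\n",
              x$model, x$mode, x$n_samples, x$n_courses))
  cat(sprintf("  MDPE  %+.2f%%  [%.2f; %.2f]\n", x$mdpe,
              x$ci_mdpe[1], x$ci_mdpe[2]))
  cat(sprintf("  MDAPE %6.2f%%  [%.2f; %.2f]\n", x$mdape,
              x$ci_mdape[1], x$ci_mdape[2]))
  invisible(x)
}
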