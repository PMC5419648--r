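#' Settings for population fitting
#'
#' @param max_iterations maximum ITSB cycles (default 200)
#' @param relative_tolerance convergence threshold on the relative change of
#'   all updated population means and SDs between cycles (default 1e-4)
#' @param map_reltol relative tolerance of the individual MAP optimizer
#' @param shrinkage stage-2 variance update: `"its"` adds the mean
#'   individual posterior log-variance to the between-subject log-variance
#'   (corrects the shrinkage of MAP estimates toward the prior); `"naive"`
#'   uses the sample variance of the point estimates only
#' @param loq_policy below-LOQ observations: `"exclude"` (default, with a
#'   logged count) or `"half_loq"` (retain at LOQ/2)
#' @param weight_at evaluate the assay-error SD at the `"observed"`
#'   (default) or `"predicted"` concentration when weighting residuals
#' @return a list of class `fit_settings`
#' @export
fit_settings <- function(max_iterations = 200, relative_tolerance = 1e-4,
                         map_reltol = 1e-12,
                         shrinkage = c("its", "naive"),
                         loq_policy = c("exclude", "half_loq"),
                         weight_at = c("observed", "predicted")) {
  stopifnot(max_iterations >= 1, relative_tolerance > 0, map_reltol > 0)
  structure(
    list(max_iterations = max_iterations,
         relative_tolerance = relative_tolerance,
         map_reltol = map_reltol,
         shrinkage = match.arg(shrinkage),
         loq_policy = match.arg(loq_policy),
         weight_at = match.arg(weight_at)),
    class = "fit_settings"
  )
}

# Internal: log-scale prior description of a model. Parameters with setting
# "Fixed", or with zero population SD, are pinned: they carry omega2 = 0 and
# are never optimized.
model_log_prior <- function(model) {
  tab <- model_param_table(model)
  mu <- omega2 <- numeric(3)
  for (i in 1:3) {
    if (tab$sd[i] > 0) {
      ln <- lnorm_from_arith(tab$mean[i], tab$sd[i])
      mu[i] <- ln$mu
      omega2[i] <- ln$omega2
    } else {
      mu[i] <- log(tab$mean[i])
      omega2[i] <- 0
    }
  }
  est <- tab$setting != "Fixed" & omega2 > 1e-12
  list(names = tab$name, mu = mu, omega2 = omega2, est = est,
       setting = tab$setting,
       fixed_value = ifelse(est, NA_real_, tab$mean))
}

# Internal: observations usable for fitting under the LOQ policy.
usable_observations <- function(record, loq_policy, loq = 0.2) {
  obs <- record$observations
  if (nrow(obs) == 0) return(obs)
  if (loq_policy == "exclude") {
    obs <- obs[!obs$below_loq, , drop = FALSE]
  } else {
    obs$conc[obs$below_loq] <- loq / 2
  }
  obs
}

# Deterministic jitter offsets (log scale) for optimizer restarts; scaled by
# the prior SD so restarts stay inside the plausible region. No RNG: results
# must be bit-identical regardless of call order.
map_jitters <- function(p) {
  base <- matrix(c(1, -1, 0.5, -0.5, 1.5), 5, p)
  sign_flip <- matrix(rep_len(c(1, -1), 5 * p), 5, p, byrow = TRUE)
  base * sign_flip
}

#' MAP Bayesian fit of one treatment course
#'
#' Minimizes the extended least-squares objective
#' `O(theta) = sum_j (Cpred(t_j) - Cobs_j)^2 / SD_j^2
#'           + sum_p (ln theta_p - mu_p)^2 / omega_p^2`
#' over the parameters with setting `"Bayesian"` or `"FPB"`; `"Fixed"`
#' parameters are held at their population value. The prior is log-normal
#' with `omega_p^2 = ln(1 + (SD_p/mean_p)^2)` and
#' `mu_p = ln(mean_p) - omega_p^2/2` (exact moment match to the arithmetic
#' population mean/SD). `SD_j` is the assay-error polynomial evaluated at
#' the observed concentration (default) or at the prediction.
#'
#' Optimization runs on log-parameters (positivity without constraints) by
#' quasi-Newton (BFGS) from the prior median, with five deterministic
#' jittered restarts on non-convergence. Log-scale posterior SDs come from
#' the curvature (inverse Hessian of `O/2`) at the optimum.
#'
#' @param record a [course_record()]
#' @param model a [population_model()]
#' @param settings a [fit_settings()] (LOQ policy, residual weighting,
#'   optimizer tolerance)
#' @param at_time time (h) at which covariates are evaluated; default the
#'   first dose start
#' @param start optional named start values `(CLm, fr, Vd)` (warm start)
#' @return an object of class `individual_fit`: the `estimate`
#'   ([individual_parameters()] with curvature-based `log_posterior_sd`),
#'   `theta`, the two objective components `wss_concentrations` and
#'   `wss_parameters`, `n_observations_used`, `n_excluded_loq` and a
#'   per-observation `residuals` table
#' @export
map_fit <- function(record, model, settings = fit_settings(),
                    at_time = NULL, start = NULL) {
  stopifnot(inherits(record, "course_record"),
            inherits(model, "population_model"))
  if (is.null(at_time)) at_time <- record$doses$start_time[1]
  prior <- model_log_prior(model)
  obs <- usable_observations(record, settings$loq_policy)
  n_excluded <- nrow(record$observations) - nrow(obs)

  cov <- record$covariates
  bw70 <- cov$weight / 70
  clcr_lh <- creatinine_clearance(cov, at_time) * 60 / 1000
  lbmc <- lean_body_mass_corrected(cov)
  doses <- record$doses

  est <- prior$est
  theta_full <- function(x) {
    th <- prior$fixed_value
    th[est] <- exp(x)
    th
  }
  finish <- function(theta, wss_c, wss_p, log_sd, resid, converged,
                     log_det_post) {
    estmt <- individual_parameters(theta, cov, at_time = at_time,
                                   log_posterior_sd = log_sd)
    structure(
      list(course_id = record$course_id, estimate = estmt,
           theta = stats::setNames(theta, prior$names),
           wss_concentrations = wss_c, wss_parameters = wss_p,
           n_observations_used = nrow(obs), n_excluded_loq = n_excluded,
           log_det_posterior_cov = log_det_post,
           residuals = resid, converged = converged),
      class = "individual_fit"
    )
  }

  log_sd0 <- stats::setNames(sqrt(prior$omega2), prior$names)
  if (nrow(obs) == 0 || !any(est)) {
    theta <- theta_full(prior$mu[est])
    resid <- data.frame(time = obs$time, c_observed = obs$conc,
                        c_predicted = numeric(nrow(obs)),
                        sd = numeric(nrow(obs)), wres = numeric(nrow(obs)))
    wss_c <- 0
    if (nrow(obs) > 0 && !any(est)) {
      ind0 <- individual_parameters(theta, cov, at_time = at_time)
      cpred <- concentration(ind0, doses, obs$time)
      sdj <- assay_sd(obs$conc, model$assay_error_coeffs)
      resid <- data.frame(time = obs$time, c_observed = obs$conc,
                          c_predicted = cpred, sd = sdj,
                          wres = (obs$conc - cpred) / sdj)
      wss_c <- sum(resid$wres^2)
    }
    return(finish(theta, wss_c, 0, log_sd0, resid, TRUE,
                  sum(log(prior$omega2[est]))))
  }

  mu_e <- prior$mu[est]
  om2_e <- prior$omega2[est]
  cobs <- obs$conc
  tobs <- obs$time
  sd_obs <- assay_sd(cobs, model$assay_error_coeffs)
  weight_obs <- settings$weight_at == "observed"

  objective <- function(x) {
    th <- theta_full(x)
    cl <- th[1] * bw70 + th[2] * clcr_lh
    v <- th[3] * lbmc
    # overflow guard: exp() of an extreme optimizer step gives 0/Inf
    if (!all(is.finite(th)) || cl <= 0 || v <= 0 || !is.finite(cl / v)) {
      return(1e12)
    }
    cpred <- conc_one_cmt(cl, v, doses, tobs)
    sdj <- if (weight_obs) sd_obs else
      assay_sd(pmax(cpred, 0), model$assay_error_coeffs)
    sum(((cpred - cobs) / sdj)^2) + sum((x - mu_e)^2 / om2_e)
  }

  # The objective is multi-modal (e.g. a slow-elimination mode can shadow
  # the true fast-elimination one), so a deterministic coarse grid over
  # +/- 2.5 prior SDs picks the basin before the quasi-Newton polish.
  if (is.null(start)) {
    p <- sum(est)
    scale <- pmax(sqrt(om2_e), 0.25)
    grid_pts <- as.matrix(expand.grid(rep(list(c(-2.5, -1.25, 0, 1.25, 2.5)), p)))
    starts <- rbind(mu_e, sweep(grid_pts %*% diag(scale, p), 2, mu_e, `+`))
    vals <- apply(starts, 1, objective)
    x0 <- starts[which.min(vals), ]
  } else {
    # warm start (ITSB cycles): the previous optimum tracks the slowly
    # moving prior, so the basin search is not repeated
    x0 <- log(start[prior$names][est])
  }
  run <- function(x) {
    stats::optim(x, objective, method = "BFGS",
                 control = list(maxit = 500, reltol = settings$map_reltol))
  }
  fit <- run(x0)
  if (fit$convergence != 0) {
    jit <- map_jitters(sum(est))
    scale <- pmax(sqrt(om2_e), 0.2)
    for (r in seq_len(nrow(jit))) {
      alt <- tryCatch(run(x0 + jit[r, ] * scale), error = function(e) NULL)
      if (!is.null(alt) && alt$value < fit$value) fit <- alt
      if (!is.null(alt) && alt$convergence == 0) break
    }
    if (fit$convergence != 0) {
      cond <- structure(
        class = c("map_fit_nonconvergence", "error", "condition"),
        list(message = sprintf(
               "MAP optimizer failed to converge for course %s after jittered restarts",
               record$course_id),
             call = sys.call(-1), best = fit))
      stop(cond)
    }
  }

  xopt <- fit$par
  th <- theta_full(xopt)
  cl <- th[1] * bw70 + th[2] * clcr_lh
  v <- th[3] * lbmc
  cpred <- conc_one_cmt(cl, v, doses, tobs)
  sdj <- if (weight_obs) sd_obs else
    assay_sd(pmax(cpred, 0), model$assay_error_coeffs)
  wss_c <- sum(((cpred - cobs) / sdj)^2)
  wss_p <- sum((xopt - mu_e)^2 / om2_e)

  # O(theta) is twice the negative log posterior (up to a constant), so the
  # Laplace covariance on the log scale is 2 * H^{-1}. The log-determinant
  # feeds the marginal-likelihood AIC; the prior covariance is the fallback
  # when the numerical Hessian is not positive definite.
  log_sd <- log_sd0
  log_det_post <- sum(log(om2_e))
  hess <- tryCatch(pracma::hessian(objective, xopt), error = function(e) NULL)
  if (!is.null(hess)) {
    cov_post <- tryCatch(2 * solve((hess + t(hess)) / 2),
                         error = function(e) NULL)
    if (!is.null(cov_post)) {
      cov_post <- as.matrix(cov_post)
      dg <- diag(cov_post)
      if (all(is.finite(dg)) && all(dg > 0)) {
        log_sd[est] <- sqrt(dg)
        ld <- determinant(cov_post, logarithm = TRUE)
        if (ld$sign > 0) log_det_post <- as.numeric(ld$modulus)
      }
    }
  }
  log_sd[!est] <- 0

  resid <- data.frame(time = tobs, c_observed = cobs, c_predicted = cpred,
                      sd = sdj, wres = (cobs - cpred) / sdj)
  finish(th, wss_c, wss_p, log_sd, resid, TRUE, log_det_post)
}

#' Iterative Two-Stage Bayesian (ITSB) population fit
#'
#' Alternates (stage 1) a MAP fit of every course against the current
#' population parameters and (stage 2) re-estimation of each
#' `"Bayesian"`-setting parameter's population mean and SD from the
#' individual estimates on the log scale, until the relative change of all
#' updated means and SDs falls below `relative_tolerance` (or
#' `max_iterations`). `"FPB"` parameters are re-estimated per individual
#' but their population values never move; `"Fixed"` parameters never move
#' at all. The stage-2 between-subject log-variance adds the mean individual
#' posterior log-variance to the sample variance of the log estimates
#' (shrinkage correction; see [fit_settings()]).
#'
#' @param cohort list of [course_record()] (>= 2; at least one parameter
#'   must have setting `"Bayesian"`)
#' @param init initial [population_model()] (the prior of the first cycle)
#' @param settings a [fit_settings()]
#' @return an object of class `population_fit`: posterior `model`, the final
#'   per-course `fits`, `aic`, `sum_wss_over_df`, `df`, `iterations_run`,
#'   `converged`, and an `iteration_trace` data.frame (means, SDs, objective
#'   per cycle)
#' @export
itsb_fit <- function(cohort, init, settings = fit_settings()) {
  stopifnot(length(cohort) >= 2, inherits(init, "population_model"))
  ids <- vapply(cohort, `[[`, "", "course_id")
  if (anyDuplicated(ids)) stop("course ids must be unique")
  cohort <- cohort[order(ids)]

  prior0 <- model_log_prior(init)
  bayes <- prior0$setting == "Bayesian" & prior0$est
  if (!any(bayes)) {
    stop("at least one parameter must have setting 'Bayesian'")
  }
  n_obs <- sum(vapply(cohort, function(r) {
    nrow(usable_observations(r, settings$loq_policy))
  }, 0L))
  n_pop <- 2L * sum(bayes)
  n_ind <- length(cohort) * sum(prior0$est)
  df <- n_obs - n_pop - n_ind
  if (df <= 0) {
    stop(sprintf(
      "over-parameterized: df = %d (= %d observations - %d population - %d individual parameters)",
      df, n_obs, n_pop, n_ind))
  }

  cur <- init
  trace <- list()
  prev_theta <- vector("list", length(cohort))
  objective_prev <- Inf
  n_increases <- 0L
  converged <- FALSE
  iter <- 0L
  fits <- NULL

  stage1 <- function(model) {
    lapply(seq_along(cohort), function(i) {
      map_fit(cohort[[i]], model, settings, start = prev_theta[[i]])
    })
  }

  for (iter in seq_len(settings$max_iterations)) {
    fits <- stage1(cur)
    prev_theta <- lapply(fits, `[[`, "theta")
    wss_total <- sum(vapply(fits, function(f) {
      f$wss_concentrations + f$wss_parameters
    }, 0))
    # The quantity ITSB descends by coordinate descent is the penalized
    # objective including the prior normalization: stage 1 minimizes the
    # WSS terms for fixed (mu, omega); the stage-2 ML update minimizes the
    # (ln theta - mu)^2/omega^2 + ln(2 pi omega^2) terms for fixed
    # estimates. The raw WSS sum alone is not monotone when priors move.
    prior_cur <- model_log_prior(cur)
    objective <- wss_total +
      length(cohort) * sum(log(2 * pi * prior_cur$omega2[prior_cur$est]))

    tab_old <- model_param_table(cur)
    new <- cur
    for (p in which(bayes)) {
      lx <- log(vapply(fits, function(f) f$theta[[p]], 0))
      mu_new <- mean(lx)
      om2_new <- mean((lx - mu_new)^2)
      if (settings$shrinkage == "its") {
        vpost <- vapply(fits, function(f) {
          f$estimate$log_posterior_sd[[p]]^2
        }, 0)
        om2_new <- om2_new + mean(vpost)
      }
      ar <- arith_from_lnorm(mu_new, om2_new)
      spec <- list(new$clm, new$fr, new$vd)[[p]]
      new[[c("clm", "fr", "vd")[p]]] <- update_param(spec, ar$mean, ar$sd)
    }
    tab_new <- model_param_table(new)

    trace[[iter]] <- data.frame(
      iteration = iter,
      clm_mean = tab_new$mean[1], clm_sd = tab_new$sd[1],
      fr_mean = tab_new$mean[2], fr_sd = tab_new$sd[2],
      vd_mean = tab_new$mean[3], vd_sd = tab_new$sd[3],
      objective = objective, wss_total = wss_total
    )

    # The shrinkage-corrected stage-2 update is not an exact coordinate
    # descent step, so the objective may wiggle by O(tolerance); only
    # increases beyond that scale count toward divergence.
    inc_tol <- 1e-8 + settings$relative_tolerance * abs(objective_prev)
    if (is.finite(objective_prev) && objective > objective_prev + inc_tol) {
      n_increases <- n_increases + 1L
      if (n_increases >= 3L) {
        cond <- structure(
          class = c("itsb_divergence", "error", "condition"),
          list(message = "ITSB objective increased on 3 consecutive iterations",
               call = sys.call(-1), trace = do.call(rbind, trace)))
        stop(cond)
      }
    } else {
      n_increases <- 0L
    }
    objective_prev <- objective

    rel <- abs(c(tab_new$mean, tab_new$sd) - c(tab_old$mean, tab_old$sd)) /
      pmax(abs(c(tab_old$mean, tab_old$sd)), 1e-8)
    rel <- rel[c(bayes, bayes)]
    cur <- new
    if (max(rel) < settings$relative_tolerance) {
      converged <- TRUE
      break
    }
  }

  # refresh individual fits against the converged population parameters so
  # the returned fits, residuals and goodness-of-fit are self-consistent
  fits <- stage1(cur)

  out <- structure(
    list(model = cur, fits = fits, df = df,
         n_observations = n_obs,
         n_population_parameters = n_pop,
         n_individual_parameters = n_ind,
         iterations_run = iter, converged = converged,
         iteration_trace = do.call(rbind, trace)),
    class = "population_fit"
  )
  gof <- goodness_of_fit(out)
  out$aic <- gof$aic
  out$sum_wss_over_df <- gof$sum_wss_over_df
  out
}

#' @export
print.population_fit <- function(x, ...) {
  cat(sprintf("<population fit: %d courses, %d observations, %s after %d iterations>\n",
              length(x$fits), x$n_observations,
              if (x$converged) "converged" else "NOT converged",
              x$iterations_run))
  print(x$model)
  cat(sprintf("  AIC = %.1f, sum WSS / df = %.3f (df = %d)\n",
              x$aic, x$sum_wss_over_df, x$df))
  invisible(x)
}

#' Goodness of fit of a population fit
#'
#' `sum WSS / df`: the summed weighted squared residuals of concentrations
#' and parameters over all courses, divided by the degrees of freedom (total
#' observations minus the number of estimated population and individual
#' parameters).
#'
#' The AIC uses the Laplace-approximate marginal likelihood of the
#' population parameters: each course contributes
#' `-2 ln L_i = wss_c + wss_p + sum_obs ln(2 pi SD^2)
#'            + sum_p ln(omega_p^2) - ln det(Cov_post)`,
#' (the integral over the individual parameters done by Laplace at the MAP
#' estimate), and `AIC = sum_i (-2 ln L_i) + 2 * n_pop` with the penalty
#' counting the estimated population parameters. A parameter whose
#' posterior equals its prior (no individual information) contributes
#' exactly zero, so adding an uninformative parameter costs the Akaike
#' penalty and never pays; this keeps the settings ranking stable where a
#' plain penalized-WSS criterion would reward collapsing population
#' variances. Absolute AIC values remain implementation-defined; only
#' differences and rankings between candidate settings on the same data are
#' meaningful.
#'
#' @param fit a `population_fit` from [itsb_fit()]
#' @return list with `aic` and `sum_wss_over_df`
#' @export
goodness_of_fit <- function(fit) {
  stopifnot(inherits(fit, "population_fit"))
  if (fit$df <= 0) stop("df <= 0: over-parameterized fit")
  prior <- model_log_prior(fit$model)
  wss_c <- vapply(fit$fits, `[[`, 0, "wss_concentrations")
  wss_p <- vapply(fit$fits, `[[`, 0, "wss_parameters")
  sum_wss <- sum(wss_c) + sum(wss_p)

  obs_norm <- sum(vapply(fit$fits, function(f) {
    if (nrow(f$residuals) == 0) 0 else sum(log(2 * pi * f$residuals$sd^2))
  }, 0))
  log_om2 <- sum(log(prior$omega2[prior$est]))
  occam <- sum(vapply(fit$fits, function(f) {
    log_om2 - f$log_det_posterior_cov
  }, 0))
  aic <- sum(wss_c) + sum(wss_p) + obs_norm + occam +
    2 * fit$n_population_parameters
  list(aic = aic, sum_wss_over_df = sum_wss / fit$df)
}

#' Nonparametric bootstrap of the population parameters
#'
#' Resamples courses with replacement, re-runs [itsb_fit()] on each
#' replicate, and returns percentile 95% confidence intervals for the
#' population mean and SD of every parameter. Replicates that fail to
#' converge are dropped and counted; more than 10% dropped is an error.
#'
#' @param cohort list of [course_record()]
#' @param init initial [population_model()]
#' @param settings a [fit_settings()]
#' @param reps bootstrap replicates (default 1000)
#' @param seed RNG seed (results are bit-reproducible given the seed)
#' @return an object of class `population_bootstrap`: a `ci` data.frame
#'   (parameter, mean_lo, mean_hi, sd_lo, sd_hi), the replicate draws, and
#'   the dropped count
#' @export
bootstrap_population <- function(cohort, init, settings = fit_settings(),
                                 reps = 1000, seed = 1) {
  stopifnot(reps >= 1)
  n <- length(cohort)
  idx <- with_seed(seed, matrix(sample.int(n, n * reps, replace = TRUE),
                                nrow = reps))
  draws <- matrix(NA_real_, reps, 6,
                  dimnames = list(NULL, c("clm_mean", "clm_sd", "fr_mean",
                                          "fr_sd", "vd_mean", "vd_sd")))
  dropped <- 0L
  for (r in seq_len(reps)) {
    boot <- cohort[idx[r, ]]
    for (i in seq_along(boot)) {
      boot[[i]]$course_id <- sprintf("%s_b%03d", boot[[i]]$course_id, i)
    }
    fit <- tryCatch(itsb_fit(boot, init, settings), error = function(e) NULL)
    if (is.null(fit) || !fit$converged) {
      dropped <- dropped + 1L
      next
    }
    tab <- model_param_table(fit$model)
    draws[r, ] <- c(tab$mean[1], tab$sd[1], tab$mean[2], tab$sd[2],
                    tab$mean[3], tab$sd[3])
  }
  if (dropped > 0.1 * reps) {
    stop(sprintf("bootstrap failed: %d of %d replicates did not converge",
                 dropped, reps))
  }
  ok <- stats::complete.cases(draws)
  q <- apply(draws[ok, , drop = FALSE], 2, stats::quantile,
             probs = c(0.025, 0.975), names = FALSE)
  ci <- data.frame(
    parameter = c("CLm", "fr", "Vd"),
    mean_lo = q[1, c(1, 3, 5)], mean_hi = q[2, c(1, 3, 5)],
    sd_lo = q[1, c(2, 4, 6)], sd_hi = q[2, c(2, 4, 6)]
  )
  structure(list(ci = ci, draws = draws[ok, , drop = FALSE],
                 n_dropped = dropped, reps = reps, seed = seed),
            class = "population_bootstrap")
}
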