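#' Body surface area (Du Bois)
#'
#' `BSA = 0.007184 * W^0.425 * H^0.725` with W in kg and H in cm.
#'
#' @param weight kg
#' @param height cm
#' @return m^2
#' @export
body_surface_area <- function(weight, height) {
  stopifnot(weight > 0, height > 0)
  0.007184 * weight^0.425 * height^0.725
}

# Serum creatinine in force at `at_time`: piecewise constant, last
# observation carried forward. Errors if the series starts after `at_time`
# (incomplete record).
scr_at <- function(cov, at_time) {
  s <- cov$creatinine
  idx <- findInterval(at_time, s$time)
  if (idx < 1) {
    stop(sprintf(
      "incomplete record: no serum creatinine at or before t = %g h", at_time))
  }
  s$scr[idx]
}

#' Creatinine clearance (Cockcroft-Gault, SI units)
#'
#' `CLcr = F * (140 - age) * W / Scr` in ml/min, with serum creatinine in
#' umol/L and sex factor F = 1.23 (male) or 1.04 (female). The weight metric
#' defaults to total body weight; lean body mass (plain or fat-corrected) is
#' available because clinical software packages differ on this choice. With
#' `normalize_bsa` the result is scaled to 1.73 m^2 body surface area
#' (Du Bois).
#'
#' @param cov a [patient_covariates()] object
#' @param at_time time (h) at which to evaluate the creatinine series
#' @param normalize_bsa normalize to 1.73 m^2 BSA?
#' @param weight_metric `"bw"` (total body weight, default), `"lbm"` or
#'   `"lbmc"`
#' @return ml/min (or ml/min/1.73 m^2 when normalized)
#' @export
creatinine_clearance <- function(cov, at_time = 0, normalize_bsa = FALSE,
                                 weight_metric = c("bw", "lbm", "lbmc")) {
  stopifnot(inherits(cov, "patient_covariates"), at_time >= 0)
  weight_metric <- match.arg(weight_metric)
  w <- switch(weight_metric,
              bw = cov$weight,
              lbm = lean_body_mass(cov),
              lbmc = lean_body_mass_corrected(cov))
  f <- if (cov$sex == "male") 1.23 else 1.04
  if (cov$age >= 140) {
    warning("age >= 140 years: creatinine clearance clamped to 0")
    return(0)
  }
  clcr <- f * (140 - cov$age) * w / scr_at(cov, at_time)
  if (normalize_bsa) {
    clcr <- clcr * 1.73 / body_surface_area(cov$weight, cov$height)
  }
  clcr
}

#' Lean body mass (sex-specific quadratic)
#'
#' `LBM = 1.10 W - 128 (W/H)^2` for males and `1.07 W - 148 (W/H)^2` for
#' females, W in kg and H in cm.
#'
#' @param cov a [patient_covariates()] object
#' @return kg
#' @export
lean_body_mass <- function(cov) {
  stopifnot(inherits(cov, "patient_covariates"))
  w <- cov$weight
  h <- cov$height
  lbm <- if (cov$sex == "male") 1.10 * w - 128 * (w / h)^2 else
    1.07 * w - 148 * (w / h)^2
  if (lbm <= 0) {
    stop("implausible anthropometrics: computed lean body mass <= 0")
  }
  lbm
}

#' Fat-corrected lean body mass (LBMc)
#'
#' The volume of distribution is expressed per kg of lean body mass
#' corrected for fat distribution: a fraction `f_fat` of the excess of total
#' body weight over lean body mass is added back,
#' `LBMc = LBM + f_fat * (W - LBM)` when `W > LBM`, else `LBMc = W`.
#'
#' @param cov a [patient_covariates()] object
#' @param f_fat fraction of excess weight counted (default 0.4)
#' @return kg
#' @export
lean_body_mass_corrected <- function(cov, f_fat = 0.4) {
  stopifnot(f_fat >= 0, f_fat <= 1)
  w <- cov$weight
  lbm <- lean_body_mass(cov)
  if (w > lbm) lbm + f_fat * (w - lbm) else w
}
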