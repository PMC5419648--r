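#' Concentration-dependent assay error
#'
#' Measurement SD as a polynomial in concentration,
#' `SD(C) = a0 + a1*C + a2*C^2`; defaults are the EMIT gentamicin assay
#' coefficients.
#'
#' @param c concentration(s), mg/L (>= 0)
#' @param coeffs polynomial coefficients `(a0, a1, a2)`
#' @return mg/L
#' @export
assay_sd <- function(c, coeffs = c(0.0766, 0.0006, 0.0064)) {
  if (any(c < 0)) stop("concentration must be >= 0")
  coeffs[1] + coeffs[2] * c + coeffs[3] * c^2
}

#' Individual pharmacokinetic parameters from covariates
#'
#' Maps the subject-level parameter triple `(CLm_i, fr_i, Vd_i)` through the
#' covariate submodels:
#' `CL = CLm_i * (BW/70) + fr_i * CLcr` (CLcr un-normalized Cockcroft-Gault,
#' converted ml/min -> L/h), `V = Vd_i * LBMc`, `k = CL/V`.
#'
#' @param theta named or positional numeric triple `(clm, fr, vd)`, all > 0
#'   (0 allowed for degenerate cases; flagged by a non-finite half-life)
#' @param cov a [patient_covariates()] object
#' @param at_time time (h) at which creatinine is evaluated (default 0)
#' @param f_fat fat-correction fraction passed to
#'   [lean_body_mass_corrected()]
#' @param log_posterior_sd optional named log-scale posterior SDs (from MAP
#'   curvature)
#' @return an object of class `individual_estimate` with fields `clm_i`,
#'   `fr_i`, `vd_i`, `CL` (L/h), `V` (L), `k` (1/h), `half_life` (h)
#' @export
individual_parameters <- function(theta, cov, at_time = 0, f_fat = 0.4,
                                  log_posterior_sd = NULL) {
  theta <- as.numeric(theta)
  stopifnot(length(theta) == 3, all(theta >= 0))
  clcr_lh <- creatinine_clearance(cov, at_time) * 60 / 1000  # ml/min -> L/h
  cl <- theta[1] * (cov$weight / 70) + theta[2] * clcr_lh
  v <- theta[3] * lean_body_mass_corrected(cov, f_fat)
  k <- if (v > 0) cl / v else NA_real_
  structure(
    list(clm_i = theta[1], fr_i = theta[2], vd_i = theta[3],
         CL = cl, V = v, k = k,
         half_life = if (is.finite(k) && k > 0) log(2) / k else Inf,
         log_posterior_sd = log_posterior_sd),
    class = "individual_estimate"
  )
}

#' @export
print.individual_estimate <- function(x, ...) {
  cat(sprintf(
    "<individual estimate: CLm %.3f, fr %.3f, Vd %.3f -> CL %.2f L/h, V %.1f L, t1/2 %.1f h>\n",
    x$clm_i, x$fr_i, x$vd_i, x$CL, x$V, x$half_life))
  invisible(x)
}

# Internal workhorse: closed-form one-compartment concentration under
# superposition of zero-order infusions with first-order elimination.
# CL and V may be vectors (parameter draws); t may be a vector; the result
# is a length(CL) x length(t) matrix (dropped to a vector when length(CL)
# is 1). No numerical integration: within an infusion of rate R starting at
# t0, C += (R/CL)(1 - exp(-k (t - t0))); afterwards the accumulated amount
# washes out mono-exponentially.
conc_one_cmt <- function(CL, V, doses, t) {
  k <- CL / V
  if (any(k <= 0)) stop("elimination rate constant must be positive (k > 0)")
  n <- length(CL)
  m <- matrix(0, n, length(t))
  for (i in seq_len(nrow(doses))) {
    t0 <- doses$start_time[i]
    Tinf <- doses$infusion_duration[i]
    R <- doses$infusion_rate[i]
    dt <- t - t0
    during <- dt > 0 & dt <= Tinf
    after <- dt > Tinf
    if (any(during)) {
      m[, during] <- m[, during] +
        (R / CL) * (1 - exp(-outer(k, dt[during])))
    }
    if (any(after)) {
      m[, after] <- m[, after] +
        (R / CL) * (1 - exp(-k * Tinf)) * exp(-outer(k, dt[after] - Tinf))
    }
  }
  if (n == 1) drop(m) else m
}

#' Predicted serum concentration
#'
#' Closed-form one-compartment concentration with first-order elimination,
#' by superposition over a train of zero-order intravenous infusions.
#' Times before all doses give 0.
#'
#' @param ind an [individual_parameters()] estimate (fields `CL`, `V`), or a
#'   list with `CL` (L/h) and `V` (L)
#' @param doses a [dose_events()] table
#' @param t evaluation time(s), h (>= 0)
#' @return mg/L, same length as `t`
#' @export
concentration <- function(ind, doses, t) {
  stopifnot(all(t >= 0))
  if (is.null(doses) || nrow(doses) == 0) return(rep(0, length(t)))
  conc_one_cmt(ind$CL, ind$V, doses, t)
}
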