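#' Log-normal moments from arithmetic mean and SD
#'
#' Population parameters are reported as arithmetic mean +/- SD but modelled
#' as log-normal between subjects. The exact moment relations give the
#' log-scale location `mu` and squared scale `omega2`:
#' `omega2 = ln(1 + (sd/mean)^2)`, `mu = ln(mean) - omega2/2`.
#'
#' @param mean arithmetic population mean (> 0)
#' @param sd arithmetic population SD (>= 0)
#' @return list with `mu`, `omega2`, `omega`
#' @export
lnorm_from_arith <- function(mean, sd) {
  stopifnot(mean > 0, sd >= 0)
  omega2 <- log1p((sd / mean)^2)
  list(mu = log(mean) - omega2 / 2, omega2 = omega2, omega = sqrt(omega2))
}

#' Arithmetic mean and SD from log-normal parameters
#'
#' Inverse of [lnorm_from_arith()].
#'
#' @param mu log-scale location
#' @param omega2 log-scale variance (>= 0)
#' @return list with `mean`, `sd`
#' @export
arith_from_lnorm <- function(mu, omega2) {
  stopifnot(omega2 >= 0)
  m <- exp(mu + omega2 / 2)
  list(mean = m, sd = m * sqrt(expm1(omega2)))
}

# Evaluate expr with the RNG seeded at `seed`, restoring the caller's RNG
# state afterwards so library functions never clobber user randomness.
with_seed <- function(seed, expr) {
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    get(".Random.seed", envir = globalenv())
  } else {
    NULL
  }
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
        rm(".Random.seed", envir = globalenv())
      }
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  })
  set.seed(seed)
  force(expr)
}

# Truncated-normal draws by inverse-CDF; used by the cohort generator.
rtruncnorm <- function(n, mean, sd, lower, upper) {
  plo <- stats::pnorm(lower, mean, sd)
  phi <- stats::pnorm(upper, mean, sd)
  stats::qnorm(stats::runif(n, plo, phi), mean, sd)
}
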