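# Independent oracles used to cross-check the closed-form model and the
# MAP optimizer. They never call the code paths they check.

# One-compartment mass balance dA/dt = R(t) - k A, C = A/V, integrated
# numerically with deSolve (lsoda). Infusion switch points are passed as
# fixed steps so the integrator does not smooth over them.
ode_concentration <- function(CL, V, doses, times) {
  k <- CL / V
  ends <- doses$start_time + doses$infusion_duration
  breaks <- sort(unique(c(0, doses$start_time, ends, times, max(times))))
  rhs <- function(t, y, parms) list(parms[["R"]] - k * y)
  A <- 0
  out_t <- 0
  out_A <- 0
  # integrate between rate discontinuities so the solver never steps
  # across a switch; the infusion rate is constant inside each segment
  for (i in seq_len(length(breaks) - 1)) {
    t0 <- breaks[i]
    t1 <- breaks[i + 1]
    mid <- (t0 + t1) / 2
    R <- sum(doses$infusion_rate[mid > doses$start_time & mid < ends])
    sol <- deSolve::lsoda(c(A = unname(A)), c(t0, t1), rhs, parms = c(R = R),
                          rtol = 1e-11, atol = 1e-13)
    A <- unname(sol[nrow(sol), 2])
    out_t <- c(out_t, t1)
    out_A <- c(out_A, A)
  }
  approx(out_t, out_A / V, xout = times)$y
}

# Exhaustive log-grid search for two-parameter MAP problems (fr, Vd; CLm
# fixed): evaluates the MAP objective on an n x n log-grid spanning
# +/- half_log natural-log units around the prior medians and returns the
# best grid point (quantization ~ half_log/n relative). Fully vectorized so
# a 400x400 grid stays fast.
grid_search_map <- function(record, model, n = 400, half_log = 0.2,
                            center = NULL) {
  prior <- gentapk:::model_log_prior(model)
  stopifnot(sum(prior$est) == 2)
  cov <- record$covariates
  bw70 <- cov$weight / 70
  clcr_lh <- creatinine_clearance(cov, record$doses$start_time[1]) * 60 / 1000
  lbmc <- lean_body_mass_corrected(cov)
  obs <- record$observations[!record$observations$below_loq, ]
  sdj <- assay_sd(obs$conc, model$assay_error_coeffs)

  idx <- which(prior$est)
  if (is.null(center)) center <- prior$mu[idx]
  ax <- seq(center[1] - half_log, center[1] + half_log, length.out = n)
  ay <- seq(center[2] - half_log, center[2] + half_log, length.out = n)
  gx <- rep(ax, times = n)
  gy <- rep(ay, each = n)
  th <- matrix(prior$fixed_value, n * n, 3, byrow = TRUE)
  th[, idx[1]] <- exp(gx)
  th[, idx[2]] <- exp(gy)
  cl <- th[, 1] * bw70 + th[, 2] * clcr_lh
  v <- th[, 3] * lbmc
  cpred <- gentapk:::conc_one_cmt(cl, v, record$doses, obs$time)
  if (nrow(obs) == 1) cpred <- matrix(cpred, ncol = 1)
  wss_c <- colSums((t(cpred) - obs$conc)^2 / sdj^2)
  wss_p <- (gx - prior$mu[idx[1]])^2 / prior$omega2[idx[1]] +
    (gy - prior$mu[idx[2]])^2 / prior$omega2[idx[2]]
  best <- which.min(wss_c + wss_p)
  out <- prior$fixed_value
  out[idx] <- exp(c(gx[best], gy[best]))
  names(out) <- prior$names
  out
}
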