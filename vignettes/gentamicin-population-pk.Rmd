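---
title: "Population pharmacokinetics of gentamicin: model, estimation and validation methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Population pharmacokinetics of gentamicin: model, estimation and validation methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(gentapk)
```

## The problem

Gentamicin is a bactericidal aminoglycoside dosed once daily (3 mg/kg as a
30-minute intravenous infusion) in adult endocarditis, aiming at peak serum
levels of 9–12 mg/L and troughs below 0.5–1 mg/L. Its half-life and volume
of distribution vary widely between patients, so therapeutic drug
monitoring (TDM) with a population pharmacokinetic (PPK) model as Bayesian
prior is standard practice. This package implements the full analysis
chain such a model lives in: the structural model with covariate
submodels, individual MAP estimation, Iterative Two-Stage Bayesian (ITSB)
population fitting with per-parameter estimation settings, external
validation by median prediction errors with bootstrap confidence
intervals, and Monte-Carlo/Bayesian forecasting for dose individualization
— exercised end-to-end on synthetic cohorts.

## Structural and covariate model

One compartment with first-order elimination and zero-order infusions.
For an infusion at rate $R$ over $[t_0, t_0+T]$,

$$C(t) = \frac{R}{CL}\left(1-e^{-k (t-t_0)}\right), \quad t_0 < t \le t_0+T,$$
$$C(t) = \frac{R}{CL}\left(1-e^{-k T}\right) e^{-k (t-t_0-T)}, \quad t > t_0+T,$$

with superposition over the dose train; $k = CL/V$. This closed form is
exact — no numerical integration is involved — and the test suite checks
it against independent ODE integration of the mass balance to $10^{-6}$
relative error.

Clearance decomposes into a non-renal and a renal part,

$$CL = CL_m \cdot \frac{BW}{70} + f_r \cdot CL_{cr},$$

with $CL_m$ (L/h per 70 kg total body weight) the metabolic clearance,
$f_r$ the renal clearance as a fraction of the Cockcroft–Gault creatinine
clearance $CL_{cr}$, and the volume of distribution expressed per kg of
corrected lean body mass, $V = V_d \cdot LBM_c$.

Covariate submodels and their defaults:

* **Cockcroft–Gault** in SI units, $CL_{cr} = F(140-\text{age})\,W/S_{cr}$
  ml/min with $S_{cr}$ in µmol/L and sex factor $F$ = 1.23 (male) / 1.04
  (female). The originating clinical software does not document its weight
  metric, so it is a configuration switch (total body weight by default;
  plain or corrected lean body mass optional). Ages ≥ 140 y clamp the
  result to zero with a warning rather than going negative. Normalization
  to 1.73 m² uses Du Bois body surface area
  ($0.007184\,W^{0.425}H^{0.725}$), the common choice in Dutch clinical
  software. A time-varying creatinine series is handled as
  piecewise-constant (last observation carried forward) — the simplest
  defensible rule.
* **Lean body mass** by the sex-specific quadratic
  $1.10W - 128 (W/H)^2$ (male) / $1.07W - 148(W/H)^2$ (female), corrected
  for fat distribution as $LBM_c = LBM + f_{fat}(W - LBM)$ with
  $f_{fat} = 0.4$ by default, capped at $W$. The exact coefficients of the
  original equations are not reproducible from the source material, so
  these conventional forms are documented defaults and both are exposed as
  configuration.
* **Assay error**: the residual SD is the EMIT polynomial
  $SD(C) = 0.0766 + 0.0006\,C + 0.0064\,C^2$ mg/L; the lower limit of
  quantification is 0.2 mg/L. Below-LOQ observations are excluded from
  fitting by default (with a logged count); retaining them at LOQ/2 is a
  configuration option.

A note on the reference patient: the worked example (male, 70 y, 76.2 kg,
174 cm, $S_{cr}$ 86 µmol/L) is sometimes quoted with a normalized
creatinine clearance of 58 ml/min/1.73 m²; no Cockcroft–Gault variant
reproduces that figure exactly from these covariates, so it is treated as
a cohort-level descriptor rather than a unit-test value.

## Individual MAP estimation

Between-subject variability is log-normal. Published population values are
arithmetic mean ± SD, so the log-scale prior uses the exact moment
relations $\omega^2 = \ln(1 + (SD/\text{mean})^2)$,
$\mu = \ln(\text{mean}) - \omega^2/2$. The MAP objective for one course is

$$O(\theta) = \sum_j \frac{(C_{pred}(t_j;\theta) - C_{obs,j})^2}{SD(C_{obs,j})^2}
            + \sum_p \frac{(\ln\theta_p - \mu_p)^2}{\omega_p^2},$$

minimized over the parameters whose setting is *Bayesian* or *FPB*;
*Fixed* parameters are pinned at their population value. The residual
weight evaluates the assay polynomial at the observed concentration by
default (weighting at the prediction is a configuration option).
Optimization runs on $\ln\theta$ (positivity without constraints) with
BFGS. The objective is multi-modal — a slow-elimination mode (low renal
fraction, large volume) can shadow the true fast-elimination one — so a
deterministic 5-point-per-dimension coarse grid over ±2.5 prior SDs picks
the basin before the quasi-Newton polish; non-convergence triggers five
deterministic jittered restarts and then an error carrying the best
solution so far. No random numbers are consumed, so results are
bit-identical regardless of call order. The log-scale posterior SDs come
from the curvature at the optimum ($2H^{-1}$, since $O$ is twice the
negative log posterior), with the prior variance as fallback when the
numerical Hessian is not positive definite.

## ITSB population fitting

Stage 1 MAP-fits every course against the current population parameters;
stage 2 re-estimates each *Bayesian* parameter's population mean and SD
from the individual estimates on the log scale. The between-subject
variance update adds the mean individual posterior log-variance to the
sample variance of the log estimates; this corrects the shrinkage of MAP
estimates toward the prior, which would otherwise understate the
variability. A "naive" mode (sample variance only) is available for
comparison. *FPB* parameters are re-estimated per individual but their
population values never move.

Convergence is declared when the relative change of every updated mean
and SD falls below $10^{-4}$ (at most 200 cycles); the source procedure
only states that iteration continues "until fixed", so this rule is the
package's own. The traced objective is the penalized criterion the
alternation actually descends — the summed WSS plus
$n\sum_p \ln(2\pi\omega_p^2)$ — because stage 2's maximum-likelihood
update minimizes exactly those terms; the raw WSS sum alone is not
monotone when the priors move. Under the naive update the trace is
provably non-increasing; the shrinkage correction perturbs it by the
order of the convergence tolerance, so divergence (an error) is only
declared after three consecutive increases beyond that scale.

Degrees of freedom follow the source definition: total concentration
measurements minus the number of estimated population parameters (mean
and SD per Bayesian parameter) and individual parameters (one per course
per Bayesian/FPB parameter); `df <= 0` is an error.

### Model selection

`sum WSS / df` is reported as defined above. For the AIC the package uses
the Laplace-approximate marginal likelihood of the population parameters:
each course contributes

$$-2\ln L_i = O(\hat\theta) + \sum_j \ln(2\pi SD_j^2)
            + \sum_p \ln\omega_p^2 - \ln\det \Sigma_{post},$$

with $\Sigma_{post}$ the curvature-based posterior covariance, and
$AIC = \sum_i -2\ln L_i + 2\,n_{pop}$. The design rationale: a simple
penalized-WSS criterion rewards two artifacts — collapsing population
variances (through $\ln \omega^2$ normalization constants) and
near-interpolation by individually-estimated parameters — and both arise
in exactly the scenario model selection must adjudicate, a parameter the
data do not support. In the marginal form a parameter whose posterior
equals its prior contributes zero, so adding an unsupported parameter
costs its Akaike penalty and never pays. Absolute AIC values remain
implementation-defined; only differences between candidate settings on
the same data are meaningful, which is how the settings grid is read.

The CLm-estimating grid variants never reach parameter stability — the
per-course data carry almost no information on non-renal clearance, so
the population value drifts indefinitely — and the grid analysis
therefore compares AIC at a fixed 40-cycle budget, at which the ranking
is stable (the AIC values move by well under one unit between 20 and 40
cycles while the gaps are several units).

### Bootstrap

Population-parameter confidence intervals come from a nonparametric
bootstrap: courses resampled with replacement, ITSB re-run per replicate,
percentile 2.5/97.5 bounds. Non-converged replicates are dropped and
counted; more than 10% dropped is an error. The reference analysis used
1000 replicates; the shipped analysis scripts use 50 with a relaxed
stability tolerance to keep the run at desk scale, and state so in their
output.

## External validation

Validation never updates population values. The default (`posterior`)
mode mirrors the one-cycle procedure used for predictive-power
assessment: one MAP fit per course against the candidate model, then
prediction at each observation time. The `a_priori` mode predicts from
population medians and ignores the observations entirely; it is retained
for sensitivity analysis. Per-sample prediction errors are
$PE_j = 100\,(C_{pred,j} - C_{obs,j})/C_{obs,j}$; MDPE (bias) and MDAPE
(precision) are sample medians (midpoint convention for even n), and
MDAPE = median(|PE|) by definition — note it is *not* bounded below by
|MDPE|, as the two medians are over different sets. Confidence intervals
are plain percentile bootstrap (no BCa), resampling individual prediction
errors by default (the resampling unit is not dictated by the source; a
by-course mode is available), 10,000 replicates.

## Forecasting and dose advice

`simulate_profile()` draws parameter triples from the log-normal
population distributions (Fixed parameters constant), maps them through
the covariate submodels and the closed-form model, and reports pointwise
2.5/50/97.5 percentiles. The band reflects parameter variability only by
default — the figure-style "95% interval" is read as parameter
uncertainty — with an option to add assay-error noise.
`bayesian_forecast()` MAP-fits the course and draws from the log-normal
Laplace approximation at the MAP (posterior mode and curvature-based
log-SDs, diagonal); full MCMC is out of scope for desk-scale TDM runtime.
With zero observations the posterior equals the prior and the forecast
reproduces the a-priori simulation draw for draw at the same seed — a
closure the tests rely on.

`recommend_dose()` exploits dose linearity: the dose hitting a target
peak (the 10.5 mg/L midpoint of the 9–12 mg/L window by default) is
`reference_dose * target / peak_at_reference`. "Peak" is operationalized
as the end-of-infusion concentration at steady state (clinical practice
sometimes samples 30 min after the infusion; the evaluation time is
configurable). The predicted steady-state trough is checked against the
window's ceiling and a too-short interval is flagged rather than
silently extended.

## The synthetic-data generator

`cohort_spec()` encodes the study conditions the pipeline is tested
under: 65 modeling courses with exactly 221 samples (14/30 for
validation), demographics drawn as truncated normals with the reported
cohort means and ranges (age 69.3 y in 32–92, weight 76.2 kg in 46–121,
height 173.9 cm in 149–193, about 1 female : 2 males; SDs back-calculated
as range width / 4 since only means and ranges are reported), serum
creatinine obtained by inverting Cockcroft–Gault from a uniform target
creatinine clearance (8.7–157.5 ml/min modeling, 28.4–181.5 validation),
2–7 once-daily 3 mg/kg doses, and a fixed-count sampling scheme — a
0.5 h post-infusion peak and a mid-interval sample (t = 1 h and 4.5 h
after dose start) on successive occasions, allocated deterministically so
the cohort totals are exact and tests are stable. True parameters are
drawn log-normally from the generating model; observation noise is
$N(0, SD(C_{true}))$ truncated below at the LOQ.

What the generator does *not* emulate: time-varying renal function within
a course (single creatinine by default), irregular clinical sampling
times, dose interruptions, assay-platform mixtures, and dialysis.
Passing recovery tests on these cohorts therefore demonstrates the
estimator's correctness under the stated design, not robustness to the
messiness of real TDM data.

## Numerical choices and problem sizes

* MAP optimizer: BFGS on log-parameters, relative tolerance $10^{-12}$,
  500 iterations; deterministic basin search as above.
* ITSB: relative tolerance $10^{-4}$ on means and SDs, 200 cycles
  maximum; warm starts from the previous cycle's estimates.
* Parameters with zero population SD (or setting Fixed) are pinned and
  excluded from estimation; an FPB parameter with SD → 0 reproduces the
  Fixed fit, and the tests assert that limit.
* The test suite runs the recovery study at 20 cohort replicates of 65
  courses, the grid-oracle comparison at 20 problems on 400×400 grids,
  validation-regime checks at 100 cohort replicates, bootstrap coverage
  at 500 replicates of 2000 resamples, and forecasts at 20,000 draws —
  sizes chosen so the whole suite completes in minutes on one core while
  Monte-Carlo error stays well inside the asserted margins.

## Known limitations

* One compartment only; no multi-compartment or nonlinear elimination,
  no dialysis clearance.
* The stage-2 update is the standard ITS refinement, not a marginal
  (FOCE/SAEM-style) mixed-effects estimator; no parameter covariances are
  estimated.
* Absolute AIC values are not comparable across implementations.
* The stepwise covariate search behind the published model structure is
  out of scope; the winning covariate structure is hard-coded.
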