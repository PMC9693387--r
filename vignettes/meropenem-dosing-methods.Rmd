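---
title: "Methods: meropenem population PK/PD simulation and estimation"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: meropenem population PK/PD simulation and estimation}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

This vignette documents the models, numerical choices and design
decisions behind `meropk`, in the spirit of a methods appendix. It
states no empirical result beyond what the package's tests and the
acceptance script themselves compute.

## Structural model and closed-form kinetics

Meropenem disposition is described by a linear two-compartment model
with zero-order infusion input, parameterized by clearance `CL`, central
and peripheral volumes `V1`, `V2`, and intercompartmental clearance `Q`.
The micro constants are `k10 = CL/V1`, `k12 = Q/V1`, `k21 = Q/V2`, and
the hybrid rates `alpha > beta > 0` are the roots of
`s^2 - (k10+k12+k21)s + k10*k21`.

Production code never integrates ODEs. For a single infusion of rate
`R0` and duration `T` starting at `t0`, the central concentration at
`t' = t - t0` is

```
C(t') = (R0/V1) [ cA (e^{-alpha u} - e^{-alpha t'})
                + cB (e^{-beta  u} - e^{-beta  t'}) ],   u = max(t' - T, 0)
cA = (alpha - k21) / (alpha (alpha - beta))
cB = (k21  - beta) / (beta  (alpha - beta))
```

which covers the infusion and post-infusion phases in one expression and
is exact under superposition for any overlapping dose pattern. The test
suite checks this solution against a stiff ODE integration
(`deSolve::lsoda`, rtol 1e-10, integrated piecewise between infusion
switch events) over 200 random parameter/regimen draws at 1e-6 relative
tolerance, plus mass balance (`CL x AUC = dose` to 0.1%) and the
continuous-infusion plateau (`Css = dose/(tau CL)` to 0.5%, evaluated
over a 120-h window because 24 h has not reached steady state).

If the discriminant of the characteristic polynomial falls below 1e-12
the slow root is perturbed by 1e-9 relative to avoid 0/0 in `cA`, `cB`;
realistic parameter sets never approach this region.

Profiles are evaluated on a regular grid augmented with every infusion
start/stop time. The default spacing of 0.05 h keeps the linear
interpolation error in %fT>MIC below 0.25% of the window (verified by a
grid-halving property test). The simulation window is 24 h from the
first dose, with no loading dose, so q8h regimens contribute three doses
and q12h regimens two.

## Population model

Typical values follow the published final model: `CL = 3.79 x 0.44^CRRT`
L/h, `V1 = 2.4` L, `V2 = 8.56` L, `Q = 21.3` L/h. Interindividual
variability is lognormal on CL and V2 only (none was estimable on V1 or
Q), with a diagonal covariance — off-diagonal terms are not modeled.
Residual error is exponential, applied as additive normal on the log
scale.

Reported variability uses the usual pharmacometric convention
`%CV = 100 sqrt(omega^2)`, so `cv_to_omega2()` inverts it as
`omega^2 = (CV/100)^2` rather than the exact lognormal
`CV = sqrt(exp(omega^2) - 1)`; at the magnitudes involved (44–47 %CV)
the difference is second order, but the convention matters when
comparing variance estimates and is stated here deliberately.

CRRT status is treated as constant over a simulated 24-h window; the
simulation scenarios are stratified by CRRT, so a within-window status
switch has no role. The packaged `base_model()` (covariate-free) exists
as the null hypothesis for the likelihood-ratio test.

## PK/PD targets

`ft_above_mic()` computes the percentage of the window with
concentration strictly above the MIC, locating crossings by linear
interpolation between adjacent grid points; a value exactly equal to the
MIC counts as not-above. Attainment of a fractional target uses the
`>=` convention (ties attain): the distinction only matters on a set of
measure zero for the 40% target.

The 100% target needs its own convention. The window starts at the
first-ever dose, where the concentration is zero, so literally requiring
concentration above the MIC over the *entire* window is unsatisfiable —
every regimen would have PTA 0. `sustained_above_mic()` therefore judges
sustained exposure from the first time the concentration reaches the
MIC: once above, it must never fall back to or below the MIC before the
end of the window. This excludes exactly the unavoidable run-in of the
first infusion and nothing else, and reproduces the published
recommendation pattern (including which standard regimens fail the
aggressive target). PTA is always computed on true (noise-free)
simulated concentrations; residual error belongs to observed data only.

## Monte Carlo PTA and nomogram

Each scenario cell samples `n = 10,000` subjects, simulates 24-h
profiles, and counts attainment; a Clopper–Pearson 95% interval
accompanies each cell, but the 90% efficiency threshold is compared to
the point estimate, as is customary. The grid covers 18 regimens
(intermittent 20-min, extended 3-h and 6-h infusion of 1 g q12h, 2 g
q12h, 0.5 g q8h, 1 g q8h, 2 g q8h; continuous q8h infusion of 0.5, 1 and
2 g), two CRRT strata, MIC 2 and 8 mg/L, and 40%/100% targets.
`recommend_regimens()` lists, per (stratum, MIC, target) cell, the
regimens with PTA at or above the threshold, ordered by total daily dose
and then infusion burden, flagging the standard-of-care intermittent
schedules.

## Synthetic study generation

`generate_study()` emulates the clinical design the model came from:
13 adult subjects by default (7 on CRRT), 1 g over 20 min q8h (q12h on
CRRT), sampled pre-dose, at 0.5, 1, 3 and 6 h post dose, and at trough.
Sampling times are jittered (Normal, sd 0.1 h, truncated inside the
interval) because actual draw times always deviate from nominal ones;
the pre-dose sample is kept exact. Observations below the 0.1 mg/L
quantification limit are flagged BLQ, recorded at the limit, and
excluded from estimation — at these doses and clearances troughs sit far
above the limit, so the only routinely-BLQ sample is the pre-first-dose
zero. True individual parameters are stored alongside the data so
estimation can be validated by parameter recovery. An optional second
occasion re-draws the support status while keeping the subject's random
effects, mimicking patients observed under two support configurations
(no interoccasion variability is modeled, as none was in the source
analysis). `rich_design()` densifies sampling to 8 points per interval
over two intervals for recovery studies.

What the generator does *not* emulate: assay error structure beyond the
exponential residual, informative sampling/dropout, time-varying CRRT,
or covariate distributions beyond the binary CRRT split. Passing
recovery tests therefore demonstrate correctness of the estimation
machinery under the stated model, not robustness to real-data
violations of it.

## FOCE-type estimation

The exponential residual model is handled by log-transforming both
observations and predictions, giving additive normal error with constant
variance on the log scale; this makes the FOCE "interaction" term benign
while retaining the method class. The marginal likelihood integrates the
per-subject random effects by Laplace approximation at the mode:

- inner problem: damped Newton on the penalized least-squares objective
  in `eta`, with a Gauss–Newton Hessian `J'J/sigma^2 + Omega^{-1}`
  (Jacobian by central differences, step 1e-4), per-subject step
  halving, convergence at step < 1e-9 or objective change < 1e-12;
- outer problem: L-BFGS-B on log-parameters with bounds 1e-4 to 1e4
  times the initial values, forward-difference steps of 1e-5 (large
  enough to dominate the inner solve's ~1e-10 noise), and an absolute
  OFV tolerance of about 2e-7. Inner modes are warm-started across
  outer iterations.

Random effects whose variance is numerically zero are profiled out, in
which case the OFV equals the closed-form lognormal -2LL — this limit is
tested exactly. On small studies the Laplace OFV is compared against an
adaptive Gauss–Hermite quadrature oracle (9 nodes per dimension,
centered at an independently-found mode) within 0.5 OFV units.

Initial estimates default to the covariate-free published values with a
neutral covariate multiplier (0.8). `fit_model(fix = ...)` holds named
parameters at their initial values, which is how the noiseless
curve-fitting limit and EBE-only computations are exercised. Relative
standard errors come from the observed-information sandwich
`A^{-1} B A^{-1}` (A = half the OFV Hessian in log-parameter space, B =
summed per-subject score outer products), falling back to `A^{-1}` when
the sandwich is singular; the log-scale SE is reported directly as RSE%.
Non-identifiable configurations (e.g. a two-compartment fit to
one-compartment data) surface as RSE > 200% rather than as hard errors.

The covariate likelihood-ratio test uses the conventional thresholds:
forward selection at ΔOFV > 3.84 (p < 0.05, 1 df) and backward retention
at ΔOFV > 6.64 (p < 0.01). Only the CRRT-on-CL term and the 1- vs
2-compartment comparison are implemented; the broader covariate screen
of the source analysis is out of scope. The power/type-I calibration
tests run 20 replicates each at 20 subjects with the densified design:
at very sparse designs (6 samples per subject) the FOCE covariate LRT
shows the well-known small-sample type-I inflation, which is a property
of the approximation, not of the implementation, and the calibration
study is designed to stay out of that regime.

Parameter uncertainty uses a nonparametric case-resampling bootstrap by
subject (percentile intervals), standing in for the sampling-importance
-resampling procedure of the source analysis. Bootstrap tests in the
suite use small replicate counts; the headline contracts (determinism
under seed, collapse at `n_boot = 1`, truth inside the interval on a
moderate study) are what is asserted.

## Diagnostics

`pcvpc()` bins observations by time since the last dose (quantile-based,
default 6 bins, bins under 3 observations merged with a warning) and
corrects each observation by `median(PRED in bin) / PRED`. The same
correction is applied to `n_sim` simulated replicates at the observed
design (default 500; the published check used 5000, which the argument
accepts — the default trades Monte Carlo smoothness for runtime, and at
500 replicates the percentile CIs are already stable relative to their
width). Reported per bin: observed 5th/50th/95th percentiles and 95%
simulation intervals for each; globally: the fraction of observations
outside the pooled simulated 5th–95th band, expected near 10% under the
generating model. Note the prediction-corrected values scale linearly
with a joint rescaling of doses and observations; the scale-free
summaries (outside fraction, percentile ratios) are the invariant
quantities.

`cwres()` implements the FOCE linearization: per subject, marginal mean
`logf(eta_hat) - J eta_hat` and covariance `J Omega J' + sigma^2 I`,
decorrelated through the Cholesky factor; with zero variances it reduces
to ordinary standardized residuals. Singular covariances flag the
subject rather than aborting.

## Problem sizes and seeds

Defaults mirror the study conditions: 10,000 subjects per PTA cell,
24-h windows, 13-subject sparse designs, 40-subject/20-replicate
recovery runs, 500-replicate VPCs with 200 subjects. Every stochastic
entry point takes an explicit `seed` and restores the caller's RNG
state; identical seeds give identical output, which the suite asserts.

## Known limitations

- Only the selected two-compartment structure is implemented (plus a
  one-compartment estimation baseline); three-compartment and nonlinear
  elimination are out of scope, as are additive/combined residual
  models for acceptance purposes.
- Total concentration is compared to the MIC; no protein-binding
  correction is applied.
- The dosing nomogram weighs neither drug stability during long
  infusions, cost, nor toxicity.
- FOCE small-sample behavior (covariate-test type-I inflation, modest
  variance-component bias at sparse designs) is inherited by
  construction; the bias bounds asserted for recovery are medians over
  replicates, not per-fit guarantees.
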