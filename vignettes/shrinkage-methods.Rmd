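---
title: "Global shrinkage estimation and sample size: models, mechanisms and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Global shrinkage estimation and sample size}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

This vignette is the package's account of the science it implements: the
quantities, the data-generating mechanisms, the numerical choices, and the
limits of what the simulations can show.

## The estimand and its estimators

For a logistic model fitted by maximum likelihood, overfitting manifests as
a calibration slope below 1 in new data: a logistic regression of outcomes
on the logit of the model's predicted risks has slope `S_opt < 1`. The
global shrinkage approach multiplies all fitted log odds ratios by an
estimate of `S_opt` and re-estimates the intercept. `S_opt` itself is
defined against the target population; the package operationalises it, as
is standard, as the calibration slope in a large validation cohort drawn
from the same mechanism (`s_opt()`). The cohort must be large enough that
sampling it is practically sampling the population: with sampled outcomes
the slope in a cohort of size `n_val` carries noise of roughly
`1/sqrt(n_val)` scale, which at `n_val = 1e5` is about 0.01 and at `1e6`
about 0.004. Where that residual noise would mask the signal of interest
(see below), `s_opt(..., use_true_p = TRUE)` computes the slope against the
true event probabilities instead — an IRLS fit with fractional responses,
which marginalises the validation outcome draw exactly and leaves only the
cohort's predictor-sampling noise.

Two estimators are implemented:

- `s_vh()`: the heuristic `1 - Q/LR`. It is cheap, closed-form, and is the
  quantity the analytic sample-size criterion targets. It is *not*
  truncated to `[0, 1]`: with weak signal `LR` can fall below `Q` and the
  estimate goes negative; such values must survive to the study level,
  where the exclusion rules treat persistently negative means as evidence
  of a degenerate scenario rather than silently clamping them.
- `s_boot()`: the bootstrap uniform shrinkage factor. Each replicate
  resamples rows with replacement (same `n`, the standard nonparametric
  bootstrap), refits, and takes the calibration slope of the replicate
  model in the *original* data; the estimate is the mean over replicates.
  A replicate fails when its resampled outcome is constant or the refit
  does not converge; failed replicates are dropped from the mean and
  counted, and the study layer excludes scenarios whose failure rate
  exceeds a threshold (default 5%). The default of 200 replicates follows
  common guidance ("usually > 200"); per-replicate accounting makes the
  exclusion rule auditable.

## Synthetic data-generating mechanisms

Scenarios freeze a random parameter set; iterations redraw data under it.
The default mechanism draws, per scenario:

- `q_meas` and `q_unmeas` uniform integers in 1..30 — models are fitted on
  the measured predictors only, so unmeasured predictors act as structured
  noise that caps achievable discrimination;
- predictors multivariate normal with either the identity covariance or a
  random correlation matrix (a Gaussian factor matrix's Gram matrix
  rescaled to unit diagonal — guaranteed positive semi-definite, with
  random dependence between every pair);
- log odds ratios uniform on (-0.5, 0.5); outcome proportion uniform on
  (0.05, 0.95) with the intercept at its logit, so the realized prevalence
  tracks the target (exactly so at null coefficients);
- development size `round(100 + W)`, `W ~ Weibull(shape 0.5, scale 2500)`,
  redrawn from scratch while above 5000 (heavy right tail, small samples
  most frequent; rounding to the nearest integer).

Under this mechanism discrimination grows with the predictor count, which
confounds "many predictors" with "high C-statistic". The alternative
mechanism (`dgm = "independent_c"`) removes the confound: no unmeasured
predictors, a target C-statistic uniform on (0.55, 0.95), and the raw
coefficients rescaled by a scalar until the model attains that target
(`rescale_coefficients_to_c()`). Because the linear predictor of a
multivariate-normal design is itself normal, the rescaling search only
needs the standard-normal shape of the linear predictor; the concordance
of a candidate scale is evaluated with outcomes marginalised (each pair
weighted by `p_i (1 - p_j)`), which makes the objective smooth and strictly
increasing in the scale, so a bracket-doubling plus bisection search (on
the log scale, tolerance 0.002 on the C-statistic by default) is reliable.

What the generator does *not* emulate: binary or skewed predictors,
missing data, variable selection, miscalibrated anticipation of the
C-statistic, and real-world covariate structure. Conclusions from these
simulations are statements about well-specified multivariate-normal
logistic mechanisms; passing tests show internal correctness and
reproduction of the published patterns under those mechanisms, not
performance guarantees on any particular clinical dataset.

## Sample-size procedures

`samplesize_analytic()` evaluates `N = p / ((S - 1) ln(1 - R2/S))` and takes the
ceiling (sample sizes are whole people; 4113.3 becomes 4114). The
anticipated Cox-Snell R-squared can be supplied directly or derived from an
anticipated C-statistic and prevalence via `c_to_r2()`, which simulates a
large cohort in which the linear predictor is normal within outcome groups
with unit variance and means `sqrt(2) * qnorm(C)` apart — the separation
under which a normal score has concordance `C` — and returns
`1 - exp(-LR/n)` of the fitted single-predictor model. The default cohort
of 1e6 keeps the conversion's Monte-Carlo error near 0.0002 on the R2
scale.

`samplesize_sim()` searches for the development size at which the *expected
optimal shrinkage* (not the heuristic) equals the target. Its mechanism
uses `p` independent standard-normal predictors with equal coefficients —
with an isotropic design only the linear-predictor scale matters, so equal
coefficients are the minimal assumption consistent with the inputs
(p, C, prevalence) — with the scale calibrated to the anticipated
C-statistic by the same marginalised-concordance search as above, rather
than by the `sqrt(2) * qnorm(C)` approximation (the two differ visibly at
high C: about 1.59 vs 1.47 at C = 0.85). Candidate sizes are evaluated by
refitting `M` development models and averaging their calibration slopes on
one fixed validation cohort; the search is bisection seeded by the
analytic criterion, with the bracket grown geometrically. Two numerical
choices matter:

- validation slopes are computed against true event probabilities
  (fractional-response IRLS). With sampled validation outcomes at
  `n_val = 1e5` the cohort contributes slope noise of about 0.02 — larger
  than the whole tolerance — and because the expected slope moves only by
  roughly `(1 - S)/n` per unit of `n`, that noise would translate into
  hundreds of participants of search error. Marginalising removes it; the
  fixed cohort then acts as common random numbers across candidates.
- a candidate within tolerance (default 0.005 on the mean slope) is
  re-evaluated with double the replicates before being accepted, so a
  lucky draw cannot end the search.

Defaults (`samplesize_sim_settings()`): M = 500 per evaluation, 1000 at
confirmation, validation 1e5, tolerance 0.005, at most 40 evaluations.
Inside study 2 the search runs once per scenario, so `run_config()` uses a
lighter profile (M = 100/300, validation 2e4, tolerance 0.01); the search
reports `converged = FALSE` rather than erroring when the cap is hit,
which in practice happens in weak-signal scenarios (population C below
about 0.65) where the target is shallow and the Monte-Carlo noise large —
those scenarios are reported in their own stratum, not dropped.

## The simulation studies

Study 1 (estimator comparison) follows, per scenario: one validation
cohort; a population fit on the measured predictors giving the population
C-statistic and Cox-Snell R-squared; then per iteration a development
dataset, the development fit, `S_VH`, `S_boot`, apparent C and R-squared,
and `S_opt` in the validation cohort. Bias is the mean of
(estimate − `S_opt`) across iterations; the Monte-Carlo standard error is
the divisor-`n` standard deviation of those deviations over the square
root of the iteration count (the divisor-`n` convention is deliberate and
asserted in tests). Study 2 (sample-size criteria) derives, per scenario,
the analytic size from the population R-squared and the simulation-based
size from the population C-statistic and realized validation prevalence
(the realized prevalence, not the scenario's target, because the
validation cohort is the operative definition of the population), then
measures `S_opt` at both sizes across iterations against the 0.9 target.

Exclusion rules mirror the degenerate-scenario patterns: study 1 drops
scenarios with negative mean heuristic/bootstrap shrinkage or apparent
R-squared, mean bootstrap shrinkage above 2, or bootstrap failure rate
above threshold; study 2 drops scenarios whose mean optimal shrinkage is
negative or above 2, and reports non-convergent searches separately.
Summaries report the mean, sd and the 2.5/25/50/75/97.5 percentiles
(linear interpolation between order statistics), overall and in
width-0.05 strata of the population C-statistic from 0.55 to 0.9.

Every scenario and iteration stream is derived from one master seed
(`derive_seed()`), so scenarios are independent work units and results do
not depend on execution order.

## Problem sizes used by the test suite

The published studies ran 15,000+ scenarios with 250 iterations,
validation cohorts of 1e6 and 200 bootstrap replicates — cluster scale.
The package's own checks run the same protocol at desk scale, chosen once
as the smallest sizes at which the qualitative claims are comfortably
outside Monte-Carlo noise: the estimator study at 120 scenarios of 40
iterations (validation 1e5, 100 bootstrap replicates), the sample-size
study at 60 scenarios of 30 iterations, and the three worked
simulation-based sample sizes at the accurate default settings. At these
sizes the asserted orderings (bootstrap dominates the heuristic on mean
absolute bias; the heuristic's bias is negative in the 0.60–0.65
C-statistic stratum and positive in 0.80–0.85; the simulation-based size
tracks the shrinkage target better than the analytic one) have several-
sigma margins. Configurations for larger runs are a `run_config()` call
away.

## Known limitations

- The calibration slope is the sole calibration metric; calibration
  intercepts are computed but not studied.
- Separation in tiny or extreme-prevalence datasets is flagged
  (standardised coefficient beyond 50) and handled by exclusion, not by
  penalised refitting.
- The simulation-based sample-size search reproduces the published worked
  examples only up to its mechanism assumptions; the upstream
  implementation's internal distributional choices are not documented, so
  agreement within a few percent is the realistic expectation.
- Applying shrinkage (`apply_shrinkage()`) re-estimates the intercept on
  the development data; the studies compare estimators of the shrinkage
  factor and do not evaluate the shrunken models themselves.
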