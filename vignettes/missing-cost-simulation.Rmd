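---
title: "Simulating and imputing missing cost data in dementia cohorts"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Simulating and imputing missing cost data in dementia cohorts}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(costmiss)
```

## The problem

Longitudinal cost-of-illness studies in Alzheimer's disease lose a third or
more of their patients over 18 months, and dropout is rarely unrelated to
cost: patients leave because they are institutionalised, because they die,
or for reasons unconnected to their disease. An analysis that simply drops
incomplete records (complete case analysis) is unbiased only when
missingness is completely at random (MCAR); when the probability of
missingness depends on observed covariates (MAR) a well-specified multiple
imputation (MI) model can remove the bias; when it depends on the
unobserved cost itself (MNAR) no imputation method that only sees the
observed data can.

`costmiss` provides a controlled laboratory for this problem: a synthetic
baseline cohort whose joint cost/covariate structure is calibrated to
published summary statistics of a large three-country observational AD
study (1497 patient/caregiver dyads, 99.4% cost-complete, mean monthly
societal cost EUR 2101 with 95% CI 1980--2222), mask generators for each
missingness mechanism, a set of estimators from naive to reason-tailored,
and a bootstrap evaluation engine that scores every estimator on bias,
sampling error and coverage.

## The synthetic cohort

Each record is a patient/caregiver dyad with age, sex, MMSE (0--26 at
enrolment; lower is worse cognition), ADCS-ADL (0--78; lower is worse
function), caregiver hours split into basic ADL, instrumental ADL and
supervision, caregiver missed-work hours and working status, and monthly
costs: patient health care, patient social care, caregiver health care,
informal care, and their sum, the total societal cost.

Choices that matter:

* **Total cost is lognormal**, moment-matched to mean EUR 2101 and
  SD EUR 2381.39. The SD is not published directly; it is derived from the
  normal-theory 95% CI half-width, `(121/1.96) * sqrt(1488)`. Cost data
  are canonically right-skewed, and this single choice is what makes the
  complete-case estimator reproduce the reported bias staircase under
  top-cost deletion (about -28% at 10% missing down to -57% at 40%): those
  biases are a property of the truncated lognormal, available in closed
  form via `truncated_lognormal_mean()`. If the source study had computed
  its CI differently (e.g. bootstrap), the derived SD would change
  slightly; the reported CI is symmetric around the mean, consistent with
  the normal-theory reading.
* **The joint structure is a Gaussian copula** over cost, total caregiver
  hours, MMSE, ADCS-ADL and age. The source material states directions
  (costs rise as cognition and function worsen) but no magnitudes; the
  defaults (cost-hours +0.6, cost-MMSE -0.35, cost-ADL -0.45, MMSE-ADL
  +0.5, cost-age +0.1, and weaker fill-ins for the remaining pairs) are
  design choices, configurable via `cohort_params(correlations = ...)`,
  and validated for positive semi-definiteness. Pearson correlations on
  the generated data are attenuated relative to the copula parameters by
  the skewed margins and the discretisation of the scores; only signs and
  rough strength are treated as meaningful.
* **Caregiver hours are lognormal with P(hours > 470/month) = 0.15** by
  default (`sdlog = 1`, `meanlog = log(470) - qnorm(0.85)`, a median of
  about 167 h/month), so the deterministic institutionalisation threshold
  rule (caregiver time above 470 h/month) lands on its 15% target rate.
  Summed hours are capped at 24 h/day (allowing the cap to be lowered to
  model sleep exclusions).
* **Component costs sum exactly to the total.** The informal-care
  component is a Beta(5, 4) share of the drawn total (mean 56%, informal
  care being the largest societal cost component in community-dwelling
  AD), and the other three components split the remainder. We deliberately
  do not construct the stored component as hours x unit cost: with the
  total-cost calibration and the hours calibration both pinned, an
  hours-based informal component would routinely exceed the drawn total
  and force negative residual components. The costing module
  (`informal_care_cost()`) recomputes hours-based valuations whenever a
  costing rule, rather than the generative split, is the object of study.
* **Baseline incompleteness (0.6%)** is assigned completely at random; the
  source does not characterise it. `analysis_set()` drops those records,
  giving 1488 of 1497 at the defaults.

What the generator does *not* emulate: country strata, longitudinal
visit-level trajectories, zero-inflation or point masses in individual
cost components, and any nonlinearity in the cost-covariate relationship
beyond what the copula induces. Tests passing on this cohort therefore
show that the estimators behave as the theory predicts under a realistic
skewed, correlated joint distribution -- not that any particular bias
magnitude would be reproduced on a different real dataset.

## Missingness mechanisms

* `mcar_mask(cohort, volume, seed)` -- exactly `round(volume * n)` records
  drawn uniformly.
* `mar_mask(cohort, volume)` -- deletes the lowest `round(volume * n)`
  records on the combined severity score `z(MMSE) + z(ADCS-ADL)`.
  Deterministic thresholding (not a probabilistic sub-model) keeps the
  volume exact, which is how the simulated volumes were defined; ties
  break by stable patient order.
* `mnar_mask(cohort, volume)` -- deletes the top `round(volume * n)`
  costs, so every missing cost exceeds every observed one.
* `dropout_pattern_mask(cohort, config, seed)` -- the mixed-reason
  18-month pattern: 15% institutionalised, 6% died, 12% lost to
  follow-up. Institutionalisation is either a logistic draw on MMSE,
  ADCS-ADL and caregiver hours (`variant = "mar_inst"`) or the
  deterministic >470 h/month caregiver-time rule (`variant = "mnar_inst"`,
  MNAR because caregiver time is withheld from the imputation models).
  Death is a logistic draw on MMSE, ADCS-ADL and age; loss to follow-up
  is uniform. Reasons are assigned in that order (institutionalised,
  died, lost to follow-up), which prevents double assignment; the order
  itself is a design choice. The logistic slopes (-0.08/MMSE point,
  -0.03/ADL point, +0.002/caregiver hour for institutionalisation;
  -0.05, -0.02, +0.05/year of age for death) are configurable defaults --
  only the covariate sets are given by the source -- and the intercepts
  are solved numerically so the mean selection probability hits the
  target rate. The MAR-variant draws select an exact count
  `round(rate * n)` with probability proportional to the logistic weight,
  keeping the realized volume deterministic at 33%; the threshold variant
  warns when its realized institutionalisation rate strays more than 20%
  relatively from the target.

## Estimators

* **Complete case** (`complete_case_estimate`): observed-only mean, SE,
  normal-theory CI.
* **Grouped means** (`grouped_means_impute`): missing costs replaced by
  the observed mean of the patient's MMSE severity group (mild 21--26,
  moderate 15--20, moderately severe/severe <15); an empty group falls
  back to the overall observed mean with a warning.
* **Fixed cost** (`fixed_cost_impute`): a flat EUR 2940/month (a published
  monthly cost of institutional care) for missing records matching a
  reason filter.
* **MI-MCMC** (`mi_mcmc`, `mi_estimate`): multivariate-normal data
  augmentation. The chain starts at the `em_mvn()` maximum-likelihood
  estimate (EM with a 1e-6 relative log-likelihood tolerance, 500
  iteration cap); each iteration draws missing cells from their
  conditional normals (I-step), then parameters from the Jeffreys-prior
  posterior -- inverse-Wishart covariance via `stats::rWishart`, normal
  mean (P-step). Defaults: 2000-iteration burn-in, one imputation every
  500 iterations, m = 5 imputations from a single chain. m is not stated
  by the source; 5 was the era-standard default of the software tradition
  the method comes from. A `chains = "multiple"` option runs m
  independent chains with one imputation each -- the source's "multiple
  chains" phrasing supports either reading, and the single-chain default
  honours the explicitly stated thinning interval. Non-positive-definite
  covariance draws are retried with jitter and logged. Imputed costs stay
  on the raw euro scale and may be negative, mirroring the normality
  assumption; a floor at zero would bias the mean upward and is not
  applied.
* **Rubin pooling** (`pool_rubin`): pooled estimate = mean of the m
  means; total variance = within + (1 + 1/m) x between; degrees of
  freedom by Rubin's formula with the Barnard--Rubin small-sample
  adjustment when complete-data df are supplied. MI CIs use the t
  quantile at the pooled df; non-MI CIs are normal-theory.
* **Combination scenarios** (`combination_impute`): Scenario A -- lost to
  follow-up by grouped means, institutionalised by MI (MMSE, ADCS-ADL,
  caregiver time), died by MI (age, MMSE, ADCS-ADL). Scenario B -- as A
  but institutionalised patients get the fixed institutional cost.
  Deterministic imputations are applied first; each reason group gets its
  own MI run on the genuinely observed rows plus that group, and the m
  completed datasets are pooled.

## The evaluation engine

`run_cell()` repeats, `n_iter` times (1000 in the full design): resample
the analysis set with replacement to its own size, re-derive the mask on
the resample, apply the estimator, record mean/SE/CI. Masks are re-derived
per resample -- thresholds re-solved -- so MAR/MNAR volumes stay exact on
every iteration; whether the original study fixed or re-solved its
thresholds is not stated, and re-solving is the reading that keeps the
missing-data volume a controlled factor. Resampling happens before
masking; the alternative order (mask once, resample the masked data) would
make the missing volume binomially random for the deterministic
mechanisms. One master seed spawns a recorded per-iteration seed stream,
so any cell replays exactly.

`summarize_cell()` reports the six outcome measures: mean cost, absolute
bias, relative bias (%), SSE (SD of iteration means -- the "true" sampling
error), SEE (mean of iteration SEs), SEE/SSE (adequacy of the SE
estimator) and coverage probability of the 95% CI. The "true" mean is the
complete analysis-set mean of the input cohort, recomputed per run.
`run_grid()` crosses mechanisms with methods and renders one summary row
per cell; `write_report()` lays the table out with costs to the euro and
CP to two decimals.

## Caregiver-time costing

`informal_care_cost()` implements the base case -- opportunity cost,
separate unit costs by caregiver working status, supervision excluded,
and the higher of costed care time or costed missed work (same unit cost
for both) -- and the three alternatives: supervision included;
replacement cost (one market unit cost for everyone, supervision
included); and working caregivers only. The default unit costs
(EUR 20/10/15 per hour for working/non-working/replacement) are
placeholders: the source defers its actual unit costs to a separate
costing reference, so set them from your own wage tables for substantive
estimates. Only the directions of the variant effects are structural
(supervision inclusion can only raise costs; working-only can only lower
them); the published magnitudes (+43% and +29% in one section, 46% in
another -- the source is internally inconsistent there and we do not
resolve it, -24% for working-only) depend on the real data's hour and
wage structure and are not calibration targets.

## Numerical and scale choices

Problem sizes in the shipped tests are chosen for desk-scale runs: MI
property checks use 200 replications of n = 250--300 with a
100-iteration burn-in and 25-iteration thinning (the chain mechanics are
identical to the defaults; for a single missing-data pattern the sampler
mixes in far fewer than 2000 iterations), bootstrap cells use 40--1000
iterations depending on how sharp the assertion is, and the
closed-form-versus-simulation check for the truncated mean uses one
million draws. The acceptance script runs the published protocol
(1000 bootstrap iterations at n = 1488) as-is.

Degenerate inputs are defined behaviour: `cost_sd = 0` collapses the cost
distribution to a point; an all-equal cost vector makes `mnar_mask` break
ties by stable patient order with a warning; a severity group with no
observed member falls back to the overall mean with a warning; volumes
must lie in [0, 1) and MI requires m >= 2.

## Known limitations

MI here assumes multivariate normality, so on the skewed cohort its
pooled mean carries a small residual bias under MAR (it still dominates
complete case, which is the comparison that matters); predictive mean
matching or propensity-score MI for small, skewed samples are out of
scope. Item-level (per-component) imputation and longitudinal
repeated-measures modelling are likewise out of scope. The threshold
variant of the dropout pattern has a binomially random institutionalised
count; only the MAR variant guarantees the exact 33% volume.
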