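# costmiss

Missing cost data are endemic in longitudinal cost-of-illness studies of
Alzheimer's disease: over 18 months roughly a third of patients drop out —
institutionalised, deceased, or simply lost to follow-up — and each of those
reasons carries a different missing-data mechanism. `costmiss` is a
simulation-and-imputation laboratory for that problem, for health economists
and biostatisticians who need to choose (or defend) a method for handling
missing total-cost data.

The package:

- generates synthetic baseline cohorts of patient/caregiver dyads whose
  joint cost/covariate distribution is calibrated to published summary
  statistics of a large European AD observational study (n = 1497, 99.4%
  cost-complete, mean monthly societal cost €2101, 95% CI €1980–2222);
- imposes missing total-cost data under MCAR, MAR (worst cognition and
  function deleted), MNAR (highest costs deleted) at any volume, and under a
  mixed-reason 18-month dropout pattern (15% institutionalised, 6% died,
  12% lost to follow-up — 33% missing overall);
- estimates the mean monthly societal cost by complete case analysis,
  grouped-means imputation, fixed-cost substitution, multiple imputation
  via multivariate-normal MCMC data augmentation (EM start, Jeffreys prior,
  2000-iteration burn-in, 500 iterations between imputations) pooled by
  Rubin's rules, and reason-tailored combinations of those methods;
- scores every estimator in a bootstrap resampling experiment on the six
  standard outcome measures: mean cost, absolute and relative bias, SSE
  (SD of iteration means), SEE (mean of iteration SEs), SEE/SSE, and 95% CI
  coverage probability;
- implements alternative informal-caregiver-time costing rules (supervision
  included, replacement vs opportunity cost, working caregivers only).

## The statistics in brief

Total cost is modelled lognormal, moment-matched to mean μ = €2101 and
SD σ = €2381 (derived from the printed CI half-width at n = 1488). Under
MNAR top-cost deletion of the fraction 1 − p, the complete-case estimator
converges to the truncated mean

E[X | X < F⁻¹(p)] = exp(m + s²/2) · Φ(Φ⁻¹(p) − s) / p,

with (m, s) the matched log-scale parameters — the closed form behind the
steep negative bias staircase the simulations reproduce. Multiple
imputation treats (cost, covariates) as multivariate normal: the I-step
draws each missing cost from its conditional normal, the P-step draws
(mean, covariance) from the Jeffreys-prior posterior (inverse-Wishart /
normal), and m completed datasets are combined by Rubin's rules,
T = W + (1 + 1/m)B, with Barnard–Rubin degrees of freedom.

## Worked example

```r
library(costmiss)

coh <- analysis_set(generate_cohort(cohort_params(seed = 1)))
nrow(coh)                  # 1488
mean(coh$cost_total)       # 2133.36  <- this cohort's "true" mean

# complete case under MNAR vs MCAR, 10% missing, 1000 bootstrap iterations
s <- summarize_cell(run_cell(coh, mechanism_spec("MNAR", 0.1),
                             "complete_case", n_iter = 1000, seed = 2))
s[c("mean_cost", "relative_bias_pct", "sse", "see", "coverage_probability")]
#   mean_cost relative_bias_pct   sse   see coverage_probability
#     1499.81             -29.7 38.15 28.61                    0
```

Deleting the top 10% of costs drags the complete-case mean to €1500, a
−29.7% bias, and the 95% CI *never* covers the true mean (CP = 0). The
same estimator under MCAR at the same volume is unbiased (+0.04%, CP 0.94).

```r
# mixed-reason dropout and a reason-tailored estimator
m <- dropout_pattern_mask(coh, dropout_config(), seed = 3)  # 33.0% missing
complete_case_estimate(coh, m)
# complete_case: mean EUR 1889.0 (SE 72.5, 95% CI 1746.9-2031.0)
combination_impute(coh, m, "B",
                   mi_config(m = 5, burn_in = 500, thin = 100, seed = 4))
# combination_B: mean EUR 2070.7 (SE 53.3, 95% CI 1966.0-2175.4)
```

Complete case underestimates by −11%; imputing each dropout reason with a
method matched to its mechanism (grouped means for lost-to-follow-up, MI
for deaths, a fixed institutional cost for the institutionalised) recovers
the mean to within −3%.

`cost_variants(coh)` compares the cohort mean under the base-case
caregiver-time rule and the three alternative valuation schemes; see the
vignette (`vignettes/missing-cost-simulation.Rmd`) for the model,
calibration and design choices in full.

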