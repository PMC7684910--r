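# qrfcost

Quantile-regression-forest analysis of high healthcare episode costs.

## The problem

Episode-level oncology expenditures are strongly right-skewed and
heteroscedastic: most 6-month chemotherapy episodes are cheap, a few are
extremely expensive, and the covariates that matter for an expensive
episode are not the ones that matter on average. Health-services questions
about "high-cost patients" are questions about the *upper quantiles* of the
cost distribution — conventionally the 90th percentile — not about the
mean.

`qrfcost` implements a pipeline for identifying and quantifying the
determinants of high episode costs from a rectangular episode table (the
eleven Oncology Care Model risk-adjustment covariates plus an episode
expenditure):

1. **Quantile regression forests.** A regression forest is grown as usual,
   but each leaf retains all response values. A prediction point receives
   per-training-observation weights from bootstrap-multiplicity-weighted
   leaf co-membership, giving a conditional CDF estimate
   F̂(y|x) = Σᵢ wᵢ(x) 1{Yᵢ ≤ y} and conditional quantiles
   Q̂τ(x) = inf{y : F̂(y|x) ≥ τ}. Out-of-bag (OOB) prediction provides an
   internal validation set.
2. **Backward stepwise selection by OOB average quantile loss (AQL).** At
   each step the least important covariate (grouped permutation importance
   in pinball-loss mode) is removed and the model refitted; the selected
   model minimizes OOB mean pinball loss ρτ(y, q) at τ = 0.9. Relative
   importance attributes shares of the null-to-optimal AQL reduction to
   each selected covariate; an R1 statistic (1 minus the check-loss ratio
   against the intercept-only quantile model) summarizes fit.
3. **Linear quantile regression effects.** The selected covariates enter a
   classical linear quantile regression at τ ∈ {0.1, 0.25, 0.5, 0.75, 0.9}
   with paired-bootstrap 95% confidence intervals, and natural cubic
   splines (3 df) profile the nonlinear effects of age and regional
   relative cost — effects in thousands of dollars, reference levels fixed.
4. **A calibrated synthetic generator.** Because real OCM extracts are
   restricted, a location-scale generator
   Y = b₀ + Σ bⱼxⱼ + (s₀ + Σ sⱼxⱼ)·ε (standardized log-normal ε) supplies
   episode tables whose marginals, cost skewness (≈ 1.67), winsorization
   bounds and quantile-varying effect profile emulate the published cohort,
   with closed-form true conditional quantiles as ground truth.

## Worked example

```r
library(qrfcost)

# a calibrated synthetic cohort at a reduced size
tab <- generate_episodes(default_generator_config(n_episodes = 800, seed = 42))

# backward stepwise selection at the high-cost quantile
trace <- backward_stepwise(tab, tau = 0.9, n_trees = 200, seed = 7)
trace
relative_importance(trace)

# quantile-varying effects of the selected covariates
effects <- effect_table(tab, trace$optimal_set,
                        taus = c(0.1, 0.5, 0.9), B = 200, seed = 11)
subset(effects, covariate == "chemo_drug")
```

```
Backward stepwise selection at tau = 0.9
Null (intercept-only) AQL: 4124.604
  step  1: 11 vars, AQL 3094.538, removed comorbidity_cat
  step  2: 10 vars, AQL 3074.169, removed insurance
  step  3:  9 vars, AQL 3024.027, removed trial
  step  4:  8 vars, AQL 3006.732, removed institutional
  step  5:  7 vars, AQL 3067.13, removed age
  step  6:  6 vars, AQL 3061.378, removed sex
  step  7:  5 vars, AQL 3039.998, removed hrr_relative_cost
  step  8:  4 vars, AQL 3062.491, removed radiation
  step  9:  3 vars, AQL 3003.495, removed surgery
  step 10:  2 vars, AQL 3253.906, removed clean_period_cat
  step 11:  1 vars, AQL 3020.952, removed chemo_drug
Optimal set (3 vars): chemo_drug, surgery, clean_period_cat

          variable delta_aql      share
1       chemo_drug 1103.6514  0.9844286
2 clean_period_cat -232.9537 -0.2077887
3          surgery  250.4110  0.2233601

    covariate level             term tau estimate    ci_low  ci_high
2  chemo_drug PartB chemo_drug.PartB 0.1 11.80985  9.437337 13.08089
7  chemo_drug PartB chemo_drug.PartB 0.5 17.66710 15.777446 20.91710
12 chemo_drug PartB chemo_drug.PartB 0.9 43.90817 32.776520 48.30967
```

Read: the chemotherapy drug class dominates — ≈98% of the null-to-optimal
AQL reduction — and its estimated cost contrast grows from ≈$11.8k at the
10th percentile to ≈$43.9k at the 90th, the quantile-varying pattern the
generator is calibrated to (shares telescope to 1 and can be negative when
an intermediate step increased the loss). At n = 800 the weaker
determinants (comorbidity, insurance, regional cost, age) fall below the
out-of-bag noise floor and are pruned early; larger cohorts retain more of
them.

The full pipeline — generate or read a table, select, quantify, write all
artifacts (selection trace JSON, elbow series, relative importance, effect
table, provenance echo) — is one call:

```r
report <- run_pipeline(run_config(generator = default_generator_config(seed = 1),
                                  n_trees = 200, output_dir = "out"))
```

## Scope notes

The package analyses analysis-ready episode tables; it does not construct
episodes from claims, price episodes, or model payment mechanics. The
synthetic generator draws covariates independently — see the methods
vignette (`vignettes/episode-cost-quantiles.Rmd`) for what that does and
does not let the tests demonstrate.
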