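---
title: "Modelling high episode costs with quantile regression forests"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Modelling high episode costs with quantile regression forests}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

## The problem

Healthcare expenditures are concentrated in a small group of high-cost
patients, and episode-level oncology cost data are strongly right-skewed and
heteroscedastic: the same covariate can have a negligible effect on a cheap
episode and a very large effect on an expensive one. Mean-based regression
averages those regimes away. `qrfcost` implements a quantile-oriented
pipeline for 6-month chemotherapy episodes of the kind collected under the
Oncology Care Model (OCM):

1. **Quantile regression forests (QRF)** estimate conditional quantiles of
   episode cost given the eleven OCM risk-adjustment covariates.
2. **Backward stepwise selection** ranks and prunes covariates by
   out-of-bag (OOB) average quantile loss (AQL) at the 90th percentile,
   the conventional high-cost threshold.
3. **Linear quantile regression** with natural cubic splines quantifies the
   effect of each selected covariate across the cost distribution.
4. A **synthetic episode generator** with closed-form conditional quantiles
   supplies calibrated data with known ground truth, since real OCM extracts
   are restricted.

## Quantile regression forests

A regression forest is grown exactly as usual: each tree on a bootstrap
sample (with replacement, sample size $n$), binary splits minimizing
within-node response variance, and a node-size floor stopping rule. The
quantile machinery then treats every tree as a partition. For a prediction
point $x$, training observation $i$ receives in tree $t$ the weight

$$ w_i^{(t)}(x) = \frac{c_{it}}{\sum_{j \in L_t(x)} c_{jt}} \;
   \mathbf{1}\{i \in L_t(x)\}, $$

where $L_t(x)$ is the leaf containing $x$ and $c_{it}$ is observation $i$'s
bootstrap multiplicity in tree $t$. Averaging over trees gives weights
$w_i(x)$ summing to one, a conditional distribution estimate
$\hat F(y \mid x) = \sum_i w_i(x) \mathbf 1\{Y_i \le y\}$, and the
conditional quantile by left-continuous inversion
$\hat Q_\tau(x) = \inf\{y : \hat F(y \mid x) \ge \tau\}$. We keep the
inf-definition with no interpolation so small worked examples are exact.
Out-of-bag prediction for a training row averages only over trees where that
row was not drawn; its own weight is automatically zero there.

Tree growing is delegated to `ranger`; the weights, quantile inversion, OOB
predictions and permutation importance are computed by this package (the
hot loops in C++).

### Loss, fit and importance

The pinball (check) loss is
$\rho_\tau(y, q) = \tau (y - q)^+ + (1 - \tau)(q - y)^+$; AQL is its mean
over observations. The goodness-of-fit statistic

$$ R_1 = 1 - \frac{\sum_i \rho_\tau(y_i, \hat Q_\tau(x_i))}
                  {\sum_i \rho_\tau(y_i, \hat q_\tau)} $$

compares the model's total check loss to the null (intercept-only) quantile
model whose predictor is the unconditional sample $\tau$-quantile. We use
the check-loss form at every $\tau$ (the Koenker–Machado convention); at
$\tau = 0.5$ it reduces to the classical absolute-deviation ratio. The null
quantile is computed in-sample: the null model has no tuning to protect
with resampling.

Permutation importance is the increase in OOB error after permuting one
covariate across rows (all dummy columns of a categorical covariate move
together, so importance attaches to covariates, not columns). Two error
modes exist. The default for selection is `pinball` at the selection
quantile: the removal ranking then targets the same functional as the
selection criterion. The `mse` mode (error of the weighted-mean prediction)
is also available, but it is blind to purely heteroscedastic effects —
covariates whose effect grows across quantiles while the mean effect stays
small — which is precisely the structure of interest in cost data, so it is
not the default.

### Backward stepwise selection

From the full model, each step fits a forest, records OOB AQL at
$\tau = 0.9$, and removes the least important covariate, down to one
covariate; the null AQL completes the trace (p + 1 recorded values).
Importance is recomputed at every step on the freshly fitted forest, which
guards against masking. Every step draws a fresh forest seed from a
deterministic sequence off the master seed, so traces are exactly
reproducible. The optimal set is the AQL argmin, ties resolved toward the
smaller model; least-importance ties resolve by covariate declaration
order.

Relative importance reads the trace backwards: the last-removed variable is
the first added on top of the null model, and the k-th added variable is
credited with the AQL drop from the (k−1)-variable model to the k-variable
model, expressed as a share of the total null-to-optimal reduction. The
shares telescope to exactly one; individual shares can be negative when a
step increased AQL.

### Linear quantile effects

The selected covariates enter a linear quantile regression at
$\tau \in \{0.1, 0.25, 0.5, 0.75, 0.9\}$, one-hot coded against fixed
reference levels (Part D drugs, quiescent 62–730-day clean period, no
radiation, no surgery, zero comorbidity flags, no Part D enrollment), age
per 10 years and HRR relative cost per 30 units, response in thousands of
dollars. Because no linear-programming quantile solver is assumed, the
check-loss minimization is performed by a majorize–minimize iteratively
reweighted least-squares scheme with a tightening smoothing parameter and a
final "vertex polish" (an exact solve through the p observations with the
smallest absolute residuals, kept when it lowers the objective). On small
instances the achieved objective is certified in the test suite against
exhaustive enumeration of basic solutions; the contract is an objective
within $10^{-6}$ relative tolerance of the optimum, not a particular
algorithm.

Confidence intervals are paired-bootstrap percentile intervals (default
B = 1000; the bootstrap method is a package choice — the interval method
used for the published tables is not stated anywhere we could follow).
Nonlinear effects of age and HRR relative cost are profiled with natural
cubic splines with 3 degrees of freedom (interior knots at evenly spaced
quantiles, boundary knots at the observed range, linear tails), reported as
effect curves relative to a reference value.

## The synthetic generator

Real OCM extracts are restricted, so the generator is a first-class module
with known ground truth. Costs follow a location-scale quantile model

$$ Y = b_0 + \textstyle\sum_j b_j x_j +
     \bigl(s_0 + \textstyle\sum_j s_j x_j\bigr)\,\varepsilon, $$

with $\varepsilon$ i.i.d. standardized log-normal (mean 0, variance 1,
shape $\sigma$), so every conditional quantile is
$b_0 + \sum b_j x_j + (s_0 + \sum s_j x_j) g(\tau)$ in closed form, and the
true quantile contrast of a binary covariate is $b_j + s_j g(\tau)$ —
growing in $\tau$ whenever $s_j > 0$, the signature pattern of cost data.

Defaults are calibrated to the published breast-cancer episode cohort:

* **Sample size** 2938 episodes.
* **Categorical marginals** equal to the published cohort frequencies
  (e.g. Part B drugs 828/2938, surgery 120/2938, radiation 257/2938). The
  published institutional-status counts are internally inconsistent
  (143 + 2924 ≠ 2938); we repair the majority class to 2795.
* **Effect profile**: for each covariate level, $(b_j, s_j)$ are solved
  from the published 10th- and 90th-quantile effect estimates via
  $b_j + s_j g(0.1) = e_{10}$, $b_j + s_j g(0.9) = e_{90}$ (thousands of
  USD). Sex, trial participation and institutional status are null
  ($b_j = s_j = 0$), mirroring the three covariates the selection excluded.
  Effects that shrink with $\tau$ (age, two insurance contrasts) force
  negative scale coefficients; the binding invariant is that the *total*
  scale stays strictly positive for every attainable covariate combination,
  which the constructor validates by enumerating category levels and
  continuous ranges.
* **Continuous marginals**: age truncated normal (72, 9) on [40, 95]; HRR
  relative cost truncated normal (0, 15) on [−45, 45]. The source tables do
  not give these distributions; they are package choices for a plausible
  Medicare population, and the HRR truncation also protects scale
  positivity.
* **Noise shape and baselines**: $\sigma = 0.8$, $b_0 = 6$, $s_0 = 10$
  (thousands). These three were calibrated once, jointly, so that the
  winsorized marginal cost skewness averages ≈ 1.67 — the value reported
  for the real cohort — while keeping only ~3% of episodes at either
  winsor bound and subgroup quartiles of a realistic order.
* **Winsorization** at [461.09, 71185.40] dollars, the repeated minima and
  maxima in the published summary table (evidence of top/bottom-coding in
  the source), applied last and toggleable. The ground-truth quantile
  oracle always refers to the *uncapped* model.

One master seed drives a documented sub-stream per covariate plus one for
the noise draw, so tables are bit-reproducible and editing one marginal
does not disturb another covariate's draws.

### What the generator does and does not emulate

It reproduces the marginal frequencies, the skewed heteroscedastic cost
distribution, and the quantile-varying effect profile. It does **not**
reproduce covariate dependence (drug class, clean period and comorbidities
are correlated in real claims; here they are independent), interactions or
non-additive effects, claims-level episode construction, or any payment
mechanics. Consequently, passing recovery tests shows the pipeline recovers
the structure it is pointed at under a faithful marginal/effect
calibration — not that it would resolve collinear real-world covariates
equally well.

## Numerical and design choices

* Clean-period day 731 falls in the ">730-or-none" class, so the three
  classes partition the integers with 730 closing the middle class; the
  new-enrollee marker takes precedence over any comorbidity flag count.
* Forest defaults: 1000 trees (200 in the selection studies below),
  `mtry = ceiling(p/3)` over encoded columns, `min_node_size = 100`. The
  node-size default is deliberately large for a forest: a leaf must hold
  enough in-bag points to resolve the target quantile, roughly
  $10/(1-\tau)$ for ~10 points above it ($\approx 100$ at $\tau = 0.9$).
  With 10-point leaves the leaf 0.9-quantile is essentially the leaf
  maximum, and in calibration probes at n = 2938 even the oracle
  signal-covariate model then loses OOB AQL to a one-covariate model;
  100-point leaves restore the expected ordering. Reduce the node size for
  central quantiles or small samples.
* Quantile inversion uses a $10^{-10}$ cumulative-weight tolerance; rows
  in-bag in every tree are masked from OOB outputs with a warning
  (probability $(1 - e^{-1})^{n_\mathrm{trees}}$ per row, negligible for
  real forests).
* A constant response yields root-only trees — a valid forest whose
  conditional quantiles collapse to the constant, not an error.
* All validation errors (unknown labels, negative costs, missing columns)
  are collected and reported together with row numbers.

## Problem sizes in the test suite

The packaged tests keep simulation studies at desk scale, as the package's
own choice of problem size: generator calibration uses 50 replicates at
n = 2938; selection-structure recovery uses 20 stepwise replicates at
n = 800 with 200 trees; linear-QR parameter recovery uses 60 replicates at
n = 5000 without winsorization (the ground-truth oracle is defined
pre-capping); bootstrap coverage uses 80 replicates at n = 600 with
B = 200. Forest oracle-equivalence checks run on forests of at most three
trees and fifty observations, where exhaustive enumeration is exact.

## Limitations

* OOB AQL differences between nested models of moderate size are of the
  same order as forest Monte-Carlo noise on data of this size, so the
  *location* of the AQL minimum (the selected model size) is intrinsically
  variable across seeds, and at reduced sample sizes null covariates can
  ride into the selected set on a lucky AQL draw. This is a property of the
  calibrated study conditions themselves: an effect profile solved from the
  published 10th/90th-quantile estimates, combined with the noise level
  required to match the observed cost skewness under scale positivity,
  yields R1 ≈ 0.33 at the 90th percentile — far below the 0.78 reported
  for the real cohort — so the selection signal here is intrinsically
  weaker than on the original data. Under a location-scale model those
  published quantities cannot be reconciled with a much higher R1.
* Linear-quantile coefficient estimates carry finite-sample bias at
  extreme quantiles under strongly skewed noise; for effects of the order
  of $100 per unit the bias at n = 5000 can exceed 5% of the effect even
  though the estimator is consistent (it vanishes by n = 20000 in the
  package's own checks).
* No simultaneous non-crossing multi-quantile estimation: fitted linear
  quantile planes can cross for extreme design points (crossings are
  monitored, not repaired).
* No honesty/subsampling forest variants and no confidence intervals for
  forest quantile predictions.
* The IRLS quantile solver certifies its objective only to tolerance; on
  designs with many tied optima the reported coefficient vector is one
  optimal vertex among several.
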