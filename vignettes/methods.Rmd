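---
title: "Methods: targeted learning of empowerment effects on antenatal care"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: targeted learning of empowerment effects on antenatal care}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
library(ancempower)
```

This vignette is the package's own account of its statistical content: the
causal model and estimands, the index constructions, the targeted estimator
and its inference, the synthetic data-generating process and its
calibration, the numerical choices, and the design decisions taken where
the design was genuinely open.

## Observed data and estimands

The observed data are O = (W, A, Y) per mother: covariates W (age, CESD
depressive score, education years, spousal education differential, child
age in months, household size, children under 15, and an asset-based wealth
component), an empowerment category A ∈ {low, medium, high} derived from a
15-item instrument, and the self-reported count Y of antenatal care (ANC)
visits. Mothers are clustered in villages.

The target parameters are the three pairwise average treatment effects
E[Y(a1) − Y(a0)] for (a1, a0) ∈ {(high, low), (high, medium),
(medium, low)}, under four outcome specifications: the visit count on the
full sample, and three binary contrasts of the categorical ANC measure
(0 / 1–3 / ≥4 visits), each analyzed on the subsample the pair implies —
≥4 vs 1–3 among mothers with at least one visit, none vs 1–3 among mothers
with at most three, ≥4 vs none among mothers with zero or at least four.
Identification requires the usual no-unmeasured-confounding and positivity
assumptions; the package protects positivity by propensity truncation
(default bounds [0.025, 0.975], configurable) and reports the fraction of
truncated cells.

## Index construction

**WEAI-style aggregate.** Items are coded so higher = more empowered. With
domain sums S_d and domain maxima M_d (d = decision, movement, assets), the
aggregate is 100 × mean_d(S_d / M_d): equal domain weights, equal item
weights within a domain (the simplest reading of an equal-domain-weight
"weighted sum score"), rescaled to [0, 100]. The score is cut at its sample
quartiles (type-7 linear-interpolation quantiles) into low / medium / high;
ties at a cutpoint go to the higher category (low is strictly below the
25th-percentile cutpoint, high is at or above the 75th). The rule is fixed
and the realized cutpoints are returned, so category assignment is exactly
reproducible; with heavy ties the realized shares can deviate from
25/50/25, which is expected behavior rather than an error.

**SWPER-style PCA indices.** The 15 items are standardized and the first
three eigenvectors of their correlation matrix retained (correlation, not
covariance, because item scales are heterogeneous). Each component is
sign-aligned to correlate positively with whichever WEAI-style subscale it
tracks most strongly; components are categorized with the same 25/75
quantile rule as the aggregate so results are comparable across index
families. Zero-variance items are dropped with a warning and recorded.

**WAMI.** Four equally weighted components, each worth 8 points of the
0–32 total: improved water/sanitation (4 points per indicator), eight
assets (1 point each), maternal education (years capped at 8 by default)
and monthly income (mapped to 0–8 by configurable band breaks). The
published construction fixes the component weights but not the income
banding, so the point allocation is exposed as a configurable weight table.
Categories use the fixed published cutoffs (high ≥ 21, medium ≥ 17 & < 21,
low < 17) rather than sample terciles.

## Nuisance estimation

Both nuisance functions are convex Super Learners: V-fold cross-validated
out-of-fold predictions per base learner (default V = 10, stratified by the
target for binary losses), meta-weights minimizing the cross-validated loss
(negative Bernoulli log-likelihood or squared error) over the probability
simplex, base learners refit on all data. The simplex optimizer uses a
softmax reparametrization from several starts and always compares its
result against every vertex, so the ensemble's CV loss never exceeds the
best single learner's. A base learner that fails to fit is dropped with a
warning; if all fail, the fit errors.

The library spans plain logistic/linear regression, a Bayesian-regularized
logistic regression (maximum a posteriori under independent Gaussian
coefficient priors, implemented as a fixed small ridge penalty), LASSO /
ridge / elastic net with internally cross-validated penalties, random
forest, gradient-boosted trees, and a spline-basis LASSO — an L1-penalized
fit on zero-order indicator bases over per-column quantile knots with a
capped basis size, a deliberately desk-scale member of the highly-adaptive
family of estimators. Fold counts, hyperparameters and library composition
are configuration, since none of them is dictated by the analysis design.

The categorical propensity is factorized as two nested binary fits:
P(A = low | W) on everyone, then P(A = high | A ≠ low, W) among the
non-low. For ordered categories cut from a latent index both stages are
monotone in the index, which a one-vs-rest decomposition is not for the
middle category; the factorization also reuses every binary learner
unchanged and yields rows that sum to one by construction.

## Targeting, inference, robustness

For each exposure level a, the initial outcome regression is updated by an
intercept-only logistic fluctuation with the clever covariate
H_a = 1(A=a)/g(a|W) as a weight (the weighted form behaves better near
positivity violations than putting H_a in the regression; the choice is
documented here and the fluctuation is a single scalar either way). The
fluctuation coefficient is found by root-finding on the score function to
near machine precision, which is what drives the post-targeting empirical
mean of each level's efficient influence curve below 1e-8 — a property the
tests assert on fitted cohorts. If the initial fit already solves the score
(saturated models), the fluctuation is exactly zero. Count outcomes are
min–max scaled to [0, 1] over their observed range before the logistic
fluctuation and back-transformed afterwards (standard bounded-outcome
targeting).

All three level means are targeted jointly on the same records, so pairwise
effects telescope exactly: ψ(high,low) = ψ(high,med) + ψ(med,low). The
pairwise binary analyses refit nuisances on the pair's subsample, matching
the conditional phrasing of the estimands ("among women who attended at
least one visit"); whether one three-level model should instead be shared
across pairs is not decidable from the design, and the subsample reading is
the one implemented.

Standard errors are village-clustered influence-curve standard errors,
se² = n⁻² Σ_c (Σ_{i∈c} EIC_i)², with 95% Wald intervals; with singleton
clusters this reduces exactly to the unclustered formula. G-computation
(main-terms logistic/linear by default, configurable formula) provides the
robustness check, with percentile confidence intervals from a nonparametric
cluster bootstrap resampling villages with replacement (default 1000
resamples). There is no outer cross-fitting (CV-TMLE) by default; the
Super Learner's internal cross-validation is the only sample splitting.

Median imputation with appended missingness indicators is applied to
covariates only — never to items, exposure or outcome — and exposure
cutpoints are computed once on the full analysis sample and reused within
strata, since stratified analyses are stratifications of one categorized
exposure, not re-categorizations. Strata below 100 mothers (configurable)
are skipped with a logged reason; nuisances are refit per stratum. The CESD
subgroup threshold defaults to the fixed value 18 (the instrument's
top-quartile cutoff in the emulated population) rather than being
recomputed per dataset, with recomputation available as an option.

## The synthetic data-generating process

The generator emulates the structure the analysis assumes, with known
truth:

- **Covariates** drawn to match the emulated population's marginals (age
  25.8 ± 5.5, CESD 13.8 ± 8.9, education 6.6 ± 3.5, education differential
  1.1 ± 3.8, household members 5.2 ± 1.9, children under 15 1.9 ± 0.8,
  child age 13.5 ± 5.3 months), with rounding/clamping to valid ranges; a
  latent wealth gradient drives eight asset indicators, sanitation and
  income (improved water is universal, as in the emulated population).
- **Latent empowerment** L = c′W_std + ε, ε ~ N(0,1): the covariate weights
  c are the confounding device. Items follow an ordinal-threshold model —
  L plus item noise (SD 1.2) cut at equally spaced thresholds — the
  simplest model producing domain-correlated ordinal items. The observed
  category is the quartile cut of the scored items.
- **Outcome**: a zero-inflated Poisson. A structural zero with probability
  π mixes with a Poisson whose log-mean is intercept + β′W_std + village
  effect + effect_medium·1(A=medium) + effect_high·1(A=high). Village
  effects are N(0, 0.2²) on the log scale (a realistic survey-scale
  intra-cluster correlation). The structural equation takes the category
  label directly, so forced-assignment counterfactuals are well defined
  even though the observational category is derived from items.
- **Missingness** is MCAR at configurable per-covariate rates (defaults:
  17/1609 on the education differential, 1/1609 on CESD) — the
  median-imputation strategy the pipeline implements is only defensible
  near MCAR, so the generator tests the mechanics, not MNAR sensitivity.

**Calibration.** Four constants were fixed once by bisection against a
large simulated draw and frozen as defaults (default seed 2019, arbitrary
but fixed): intercept 1.0726 and zero inflation 0.0962 so the
default cohort has mean visits 3.1 with 14% zeros; effect_high 0.2318 so
the true high-vs-low contrast on P(≥4 | ≥1 visit) is 0.150; effect_medium
0.0956 so medium-vs-low is 0.060.

**Truth.** True counterfactual means are computed by forcing each exposure
level in the structural model over a large Monte-Carlo draw of covariates
and village effects. For the count outcome the per-mother mean (1−π)·μ_a
is averaged over everyone; for the binary pairs the analytic conditional
probability under the zero-inflated Poisson law (e.g. P(Poisson(μ_a) ≥ 4)
/ (1 − e^{−μ_a}) for ≥4 vs 1–3) is averaged over the observational
subsample the pair implies — the statistical parameter the subsample
analysis targets. Averaging analytic conditionals rather than simulated
draws removes one layer of Monte-Carlo noise. A small discrepancy remains
in principle because conditioning on observed subsample membership ties
the village effect to the realized exposure; recovery experiments bound it
empirically below 0.002 on a 0.15 contrast.

**What the generator does not emulate.** Multistage sampling weights (the
emulated analysis uses none), item-level wording effects (per-item level
counts are schema-configurable because the instrument's item coding is not
public), MNAR missingness, and outcome misreporting. Passing tests
therefore demonstrate correctness of the machinery under the assumed
structure, not robustness to violations real data may carry.

## Validation experiments and problem sizes

The Monte-Carlo harness runs three experiment families, with sizes chosen
as the package's compromise between Monte-Carlo error and turnaround:

- **Recovery**: replicated generate→analyze cycles at n = 2000 (500
  replicates in the test suite) against the true 0.15 contrast; the TMLE
  with the fast learner library shows |bias| < 0.01 and CI coverage within
  [0.92, 0.98].
- **Double robustness**: a constructed configuration (`dgp_config_dr`)
  makes education a deliberately dominant confounder (latent weight 0.45,
  outcome weight 0.28 — strong enough that the omitted-confounder plug-in
  is biased by ~0.16, moderate enough that positivity holds comfortably
  inside the truncation bounds). Omitting it from the outcome model leaves
  TMLE within 0.01 of truth at n = 5000 while the plug-in exceeds 0.03
  bias; omitting it from both nuisances breaks TMLE too, as theory
  predicts.
- **Saturated equivalence**: on a shipped 18-row discrete cohort with
  saturated nuisances, TMLE, G-computation and hand-computed
  nonparametric standardization agree to 1e-6 (observed: ~1e-13).

Replicated experiments default to the single plain-regression learner
(cross-validation skipped for a singleton library): with approximately
correctly specified nuisances the ensemble adds nothing but runtime, and
tree ensembles across hundreds of replicates are outside desk scale. The
full library remains available per call.

## Numerical choices and degenerate inputs

- Probabilities are clamped at 1e-12 before logit transforms; Super
  Learner binary predictions are bounded to [1e-6, 1 − 1e-6].
- The fluctuation root is accepted at zero when the initial score is
  already below 1e-9 relative to the total clever-covariate mass (the
  saturated case); if no interior root exists (outcome constant within a
  level), the minimizer of |score| on [−30, 30] is used and the residual
  score must be negligible, otherwise the fit errors with diagnostics.
- Constant outcome vectors error in the outcome regression ("degenerate
  fit"); constant score vectors error in quantile categorization; an
  exposure level with fewer than 10 observations errors with advice to
  collapse the analysis.
- Zero-variance covariate columns are dropped within strata before model
  fitting; the plain-regression learner prunes linearly dependent columns
  by QR so prediction is defined on any new data.
- All randomness is seed-controlled: the generator takes a seed in its
  configuration, replicate seeds are derived deterministically from a
  master seed, and Super Learner fold assignment is seeded.

## Known limitations

Cross-sectional, observational identification: nothing here removes
unmeasured confounding. The spline-basis LASSO is a capped surrogate, not
a full highly adaptive LASSO. Subsample estimands for the binary pairs
condition on observed (not counterfactual) subsample membership. The
influence-curve variance ignores the sampling variability of the exposure
cutpoints and of the Super Learner itself; the recovery experiments show
the resulting intervals are mildly conservative at the default
configuration (empirical coverage ~0.97).
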