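# ancempower

Targeted learning of women's empowerment effects on antenatal care (ANC)
attendance in clustered household surveys.

## The problem

In rural South Asia most women attend at least one antenatal care visit but
far fewer reach the four visits national guidelines recommend, and low
empowerment — limited say in household decisions, restricted movement, little
control over assets — is a plausible barrier. This package implements, as a
tested and reusable pipeline, an observational analysis of that question in
a counterfactual framework: it asks how ANC attendance would change if every
woman in the population were assigned low, medium or high empowerment, where
the empowerment category is derived from a 15-item survey instrument (7
household decision-making items, 3 freedom-of-movement items, 5
control-over-assets items).

Because the survey data such analyses use are typically access-restricted,
the package ships a calibrated synthetic cohort generator with known
counterfactual ground truth, so every stage — index construction, ensemble
nuisance estimation, targeted estimation, clustered inference, subgroup
stratification — is exercised and validated end to end without any download.

## What it computes

**Exposure.** A WEAI-style aggregate score: items are summed within each
domain, each domain sum is divided by its maximum, the three domain
proportions are averaged with equal weight and rescaled to 0–100; the score
is cut at its sample quartiles into low (bottom 25%), medium (middle 50%)
and high (top 25%). Subscale scores, SWPER-style principal-component indices
(first three components of the item correlation matrix, sign-aligned to the
matching subscale) and the 0–32 WAMI socioeconomic index (fixed cutoffs:
high ≥ 21, medium ≥ 17 & < 21, low < 17) are also constructed.

**Estimands.** For exposure levels a ∈ {low, medium, high} and counterfactual
outcome Y(a), the three pairwise population average treatment effects

    ATE(a1, a0) = E[Y(a1) − Y(a0)] = E_W[ E(Y | A=a1, W) − E(Y | A=a0, W) ]

for four outcome specifications: the visit count, and the three pairwise
binary contrasts of the categorical ANC measure (≥4 vs 1–3 among women with
at least one visit; none vs 1–3 among women with at most three; ≥4 vs none
among women with zero or ≥4 visits).

**Estimator.** Targeted maximum likelihood estimation (TMLE): an initial
outcome regression Q̄(A, W) and propensity score g(a | W) — each a convex
Super Learner over a configurable library (logistic/linear regression,
Bayesian-regularized logistic regression, LASSO, ridge, elastic net, random
forest, gradient boosting, spline-basis LASSO) — followed by one
intercept-only logistic fluctuation per exposure level with the clever
covariate H_a = 1(A=a)/g(a|W) as weight. Standard errors come from the
efficient influence curve, clustered at the village level:
se² = n⁻² Σ_villages (Σ_{i∈village} EIC_i)². Parametric G-computation with a
village bootstrap serves as a robustness check, and a Monte-Carlo harness
establishes parameter recovery, double robustness and CI coverage.

## Worked example

```r
library(ancempower)

cfg    <- dgp_config()                      # calibrated defaults: 1609 mothers, 109 villages
cohort <- inject_missingness(generate_cohort(cfg))
res    <- run_analysis(cohort$records, indices = "aggregate",
                       outcomes = "ge4_vs_1to3",
                       learners = c("glm", "lasso", "ridge"),
                       stratify = FALSE)
subset(res$estimates, estimator == "tmle",
       select = c(comparison, psi, ci_lower, ci_upper))
```

On the default cohort this prints (`analysis/03_primary_ates.R` output):

```
ge4_vs_1to3   high_vs_low    psi +0.144 (95% CI +0.059, +0.230)
ge4_vs_1to3   high_vs_medium psi +0.092 (95% CI +0.023, +0.162)
ge4_vs_1to3   medium_vs_low  psi +0.052 (95% CI -0.020, +0.123)
```

i.e. setting every woman's empowerment to high rather than low would raise
the probability of attending ≥4 visits (among women attending at least one)
by 14.4 percentage points; the generator's true contrast for this
configuration is +0.150, inside the reported interval. The effects are
exactly additive across the gradient because the three level means are
targeted jointly.

The numbered scripts under `analysis/` run the full workflow: `01_simulate`
(draw and write the cohort), `02_describe` (indices and a Table-1-style
descriptive summary), `03_primary_ates` (full-sample TMLE for the aggregate
index and the three subscales, plus G-computation), `04_subgroups`
(WAMI-tercile and risk-subgroup stratification), `05_simstudy` (Monte-Carlo
validation: on 100 replicates at n = 2000 the TMLE shows bias −0.001 against
the true 0.146 contrast with 97% CI coverage; with the dominant confounder
omitted from the outcome model the plug-in is biased by +0.157 while TMLE
stays at +0.005). Each writes its tables under `results/`.

## Layout

- `R/` — generator (`synthdata`), index construction (`indices`), Super
  Learner and nuisance fits (`learners`, `super_learner`, `nuisance`),
  TMLE / G-computation / clustered variance (`tmle`), orchestration
  (`pipeline`), Monte-Carlo harness (`simstudy`).
- `vignettes/methods.Rmd` — the model, its assumptions, tuning parameters
  and design decisions.
- `inst/extdata/` — an 18-row discrete toy cohort with hand-computed
  standardized means, used as an exactness oracle for the estimators.
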