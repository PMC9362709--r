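---
title: "Constructing hedonically weighted child well-being indices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Constructing hedonically weighted child well-being indices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(cati)
```

## The problem

Composite indices of child and adolescent well-being are usually built by
counting indicators with equal weights chosen by expert judgment.  The
Child and Adolescent Thriving Index (CATI) instead derives its weights
*hedonically*: each binary childhood indicator (on-time high-school
graduation, food security, not smoking in adolescence, ...) is weighted by
the strength of its association with how the same people later rate their
own lives, measured by five subjective well-being scales observed in young
adulthood — flourishing (`fl`), psychological distress (`pd`), economic
worry (`wr`), social anxiety (`sa`) and life satisfaction (`ls`).

This package implements that construction as a reusable pipeline.  Because
the panel data it was developed on is access-restricted, the package ships
a synthetic cohort generator with the same statistical structure and known
ground truth, so every stage can be exercised and tested end to end.

## The model

All components are coded in positive framing (1 = good status), so a
well-functioning component should raise `fl` and `ls` and lower `pd`,
`wr` and `sa`.  The pipeline is:

1. **Multiple imputation.** Roughly 40% of realistic cohorts have at least
   one missing cell; chained equations produce `m = 20` completed copies
   (binary cells by Bayesian logistic draws, continuous cells by normal
   linear draws, 10 cycles).  Estimates are pooled with Rubin's rules and
   Barnard–Rubin degrees of freedom.
2. **Scale preprocessing.** Each subjective scale is averaged within person
   across its observed waves, then z-scored.
3. **Selection, step one.** Per imputation and per scale, an adaptive
   LASSO (ridge pilot on a seeded 80% training split, penalty weights
   $1/|\hat\beta_{pilot}|$, 100 log-spaced penalties, penalty chosen to
   minimize held-out MSE on the remaining 20%, demographics unpenalized,
   no attrition weights) screens the candidate components.  A component
   survives only if kept in at least half the imputations (10 of 20).
4. **Selection, step two.** Attrition-weighted least squares of the
   standardized scale on the surviving components plus demographics,
   pooled across imputations; components are removed one at a time —
   wrong-signed ones first (largest p first), then any with pooled
   p > 0.25 — until a fixed point.
5. **Double weighting.** With first-principal-component loadings
   $\lambda_j$ of the five scales and pooled coefficients $\beta_{j,z}$
   (0 where removed), the raw weight of component $z$ is
   $$W_z = \tfrac{1}{5}\sum_{j} |\lambda_j \, \beta_{j,z}|,$$
   normalized so the weights sum to 1.  The absolute value is essential:
   the distress/worry/anxiety coefficients are negative where the
   flourishing/life-satisfaction ones are positive, and without it the
   terms would cancel.  The divisor stays 5 even for components that
   survive in fewer equations, which is exactly what shrinks weakly
   supported components like preschool attendance toward small weights.
6. **Scoring.** $\mathrm{CATI}_i = \sum_z w_z\,\mathrm{Comp}_{i,z} \in
   [0,1]$, plus a standardized version for validity models.
7. **Validity.** Weighted logistic models give the average marginal effect
   of a one-SD score increase on each binary young-adult outcome
   (finite-difference predictive margins, influence-function variances,
   MI-pooled); a weighted Poisson model with HC0 sandwich errors gives
   the percent change in peak earnings, $100(e^{\beta}-1)$; partial
   $R^2$ is Efron's $R^2$ of the full minus the covariates-only model.
   An equal-weight count index is the standard comparator, and a stacked
   influence-function (seemingly-unrelated) test compares marginal
   effects of two indices fitted on the same respondents.

## A worked example

```{r, eval = FALSE}
cfg <- sim_config(n_children = 2000, seed = 1)
cohort <- apply_missingness(generate_cohort(cfg), cfg)
res <- run_pipeline(cohort, cati_config(m = 20, seed = 1))
res$weights
res$validity$fair_poor_health
```

The bundled golden fixture reproduces the published CATI 1.0 weights from
the published loadings and coefficients:

```{r}
golden_check()
```

## What the generator emulates, and what it does not

`sim_config()` defaults describe a PSID-like cohort: 13 individual and 6
contextual binary components at the published prevalences (e.g. food
insecurity 13.3%, late graduation 20.0%); five scales on their native
ranges (life satisfaction is a 1–5 integer item) driven by one
standard-normal latent well-being factor, with loadings and wave-noise
calibrated so the first principal component explains roughly half the
scale variance (first eigenvalue near 2.6, matching the published 2.62);
about 40% of rows with at least one missing cell under a MAR mechanism
driven only by age, sex and the attrition weight; and young-adult outcomes
(fair/poor health 21.2%, depression 29.3%, peak earnings with mean near
$31k and SD of similar size via a log-normal model).

Deliberate simplifications: components are independent given the latent
factor (real indicators are themselves correlated); there is no
multi-generational family clustering or complex survey design (strata and
PSUs are out of scope; only the attrition weights are used); attrition
weights are only loosely calibrated, since attrition was reported to have
minor effects; and the MAR driver is exactly recoverable by the imputation
models, which is the favorable case for MI.  Passing tests on this cohort
therefore show the pipeline's correctness and calibration under its own
assumptions, not robustness to clustered or non-ignorable missingness.

## Ground truth and its estimand

`true_weights()` applies the double-weighting formula analytically to a
configuration: effects are first divided by the analytic SD of the
wave-averaged scale (because the pipeline standardizes scales before every
fit) and combined with the population first-PC loadings of the analytic
scale correlation matrix, which includes the component-induced covariance.
With equal loading magnitudes and a shared sign pattern this reduces to
normalized effect magnitudes, so recovery tests read directly against the
configured proportions.  The life-satisfaction integer rounding is ignored
by the analytic covariance; configurations used for recovery testing keep
scales continuous so the estimand is exact.

## Numerical and design choices

- **Pilot estimator**: ridge with a small fixed penalty (0.01 per
  observation) rather than OLS, so pilots exist under collinearity among
  components; ridge shrinks pilots nearly proportionally, so the adaptive
  penalty *ratios* are essentially those of OLS pilots.
- **Elimination order**: wrong-signed components are removed before
  large-p ones; both rules are part of the published procedure but their
  order is not, and sign violations are the interpretability problem the
  rule exists to fix, so they go first.  The one-at-a-time order makes the
  procedure deterministic given the imputation set.
- **PCA under MI**: per-imputation correlation matrices of the
  standardized scales are averaged, then eigendecomposed once — symmetric
  in the imputations and deterministic.  Loadings are sign-fixed so `fl`
  loads positively; a second eigenvalue above 1 triggers a warning since
  the single-component design would then be questionable.
- **Complete-data shortcut**: when the input cohort has no missing cells,
  all `m` copies are identical, so pooled regressions are fitted once and
  replicated (between-imputation variance is exactly 0); the LASSO stage
  still runs per imputation because its 80/20 split is re-drawn each time.
- **Seeds**: one master seed feeds every stage through named substreams
  (imputation, per-imputation splits, bootstrap), so stages are
  individually reproducible and identical configurations give identical
  artifacts.
- **Binary outcome family**: logistic, with probit-free finite-difference
  margins (`p(score+1) - p(score)` averaged with attrition weights); a
  derivative-based AME is available.  Efron's $R^2$ is used for binary
  outcomes because it coincides with ordinary $R^2$ in the linear case,
  keeping full-minus-base partial $R^2$ comparable across outcome types.
- **Earnings**: quasi-Poisson point estimates (identical to Poisson) with
  HC0 sandwich variances; effects are reported as percent change per SD,
  with the dollar-scale average marginal effect alongside.
- **Degenerate inputs**: zero-variance scales, components with no observed
  cases, all-zero weight vectors and mismatched component names are
  refused with the offending name; a pilot coefficient of exactly zero
  excludes the component (infinite penalty) rather than erroring; constant
  design columns are dropped with a warning.

## Test problem sizes

The test suite exercises the pipeline at sizes chosen to keep the full run
in a few minutes on one core while leaving sampling error well below the
asserted tolerances: unit tests use cohorts of 100–6,000; the
parameter-recovery exercise uses complete cohorts of n = 20,000 over 20
seeds with m = 20; the screening operating characteristics use 50
replicates at n = 2,000; the null calibration of the index comparison uses
200 replicates at n = 800.

## Known limitations

- The selection procedure's generous retention rule (pooled p ≤ 0.25)
  deliberately trades specificity for sensitivity.  With five benchmark
  equations, a truly uninformative component has a nontrivial chance of
  surviving in at least one equation and so receiving a small positive
  weight; the recovery tests show such surviving null weights stay small
  (within ±0.03 of their true zero) even when they are not exactly zero.
- Additive scoring implies substitutability between components; no
  geometric or multiplicative aggregation is offered.
- Post-selection inference is not corrected; reported standard errors for
  selected coefficients inherit the usual post-LASSO caveats.
- The seemingly-unrelated comparison pools per-imputation differences and
  influence-function variances; small-sample behavior beyond the null
  calibration test has not been characterized.
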