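# cati

Construction and validation of hedonically weighted child and adolescent
well-being indices.

Most composite indices of child well-being (KIDS COUNT-style counts of
positive indicators) weight their components equally, by expert judgment.
The Child and Adolescent Thriving Index (CATI) approach implemented here
derives the weights from the data instead: each binary childhood indicator
is weighted by the strength of its association with five subjective
well-being scales the same individuals report in young adulthood —
flourishing (fl), psychological distress (pd), economic worry (wr), social
anxiety (sa) and life satisfaction (ls).  The package is written for
researchers building or stress-testing such indices on longitudinal cohort
data.

## The method

With first-principal-component loadings λ_j of the five standardized
scales and pooled regression coefficients β_{j,z} of scale j on component
z (0 where the component was removed by model selection), the weight of
component z is

    W_z = (1/5) Σ_j |λ_j β_{j,z}|,      w_z = W_z / Σ_z W_z

and a child's index score is CATI_i = Σ_z w_z Comp_{i,z} ∈ [0, 1].
The coefficients come from a two-step selection under multiple imputation
(m = 20 chained-equation copies): per-imputation adaptive LASSO screens
(80/20 train/validation split, penalty weights 1/|pilot|, demographics
unpenalized) with a 10-of-20 retention rule, then attrition-weighted
pooled regressions with one-at-a-time backward elimination of wrong-signed
or p > 0.25 components.  Predictive validity is quantified by average
marginal effects of a 1-SD score increase on young-adult outcomes, partial
R², and robust-Poisson percent changes in peak earnings.

Because the panel data the method was developed on is access-restricted,
the package includes a synthetic cohort generator (`sim_config()`,
`generate_cohort()`, `apply_missingness()`) with the same statistical
structure and known ground-truth weights (`true_weights()`), so the whole
pipeline is testable end to end.

## Worked example

```r
library(cati)

cfg    <- sim_config(n_children = 2000, seed = 1)   # PSID-like defaults
cohort <- apply_missingness(generate_cohort(cfg), cfg)
res    <- run_pipeline(cohort, cati_config(m = 20, seed = 1))
res$weights
#> Normalized index weights (sum to 1):
#>             component weight
#>           food_secure  0.193
#>    attended_preschool  0.027
#>       grad_hs_on_time  0.190
#>       math_proficient  0.099
#>    reading_proficient  0.066
#>   non_low_birthweight  0.054
#>             non_obese  0.069
#>  not_fair_poor_health  0.000
#>           didnt_smoke  0.153
#>           didnt_drink  0.022
#>   didnt_try_marijuana  0.079
#>        never_pregnant  0.000
#>        never_arrested  0.048
res$validity$fair_poor_health
#> ever_fair_poor_health ~ cati: marginal effect -0.0300 [-0.0458, -0.0142], p = 0.000202
#>   partial R^2 = 0.0067 (0.0108 vs 0.0041)
```

The weights are the normalized index weights (summing to 1); the largest
fall on the components given the largest true effects in the generator
(food security, on-time graduation, not smoking), while two uninformative
components are removed outright.  The marginal effect says a
one-standard-deviation increase in the index is associated with a 3.0
percentage-point lower probability of ever reporting fair or poor health
in young adulthood, and the index adds 0.007 to the demographics-only R².

The golden check reconstructs the published CATI 1.0 weights from the
bundled published loadings and per-scale coefficients:

```r
golden_check()
#> Golden check of the double-weighting reconstruction:
#>             component computed published   delta pass
#>    attended_preschool   0.0252     0.025  0.0002 TRUE
#>           didnt_smoke   0.1922     0.192  0.0002 TRUE
#>   didnt_try_marijuana   0.0678     0.069 -0.0012 TRUE
#>           food_secure   0.1994     0.199  0.0004 TRUE
#>       grad_hs_on_time   0.2865     0.285  0.0015 TRUE
#>       math_proficient   0.0510     0.052 -0.0010 TRUE
#>        never_arrested   0.0262     0.027 -0.0008 TRUE
#>   non_low_birthweight   0.0512     0.052 -0.0008 TRUE
#>             non_obese   0.0196     0.020 -0.0004 TRUE
#>  not_fair_poor_health   0.0262     0.027 -0.0008 TRUE
#>    reading_proficient   0.0546     0.054  0.0006 TRUE
#> top-3 weight share: 0.678; all within tolerance: TRUE
```

A thin command-line front end is installed at
`inst/cli/cati-cli.R` (subcommands `simulate`, `run-all`,
`golden-check`).

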