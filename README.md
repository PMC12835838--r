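# intermaihda

Intersectional MAIHDA (multilevel analysis of individual heterogeneity and
discriminatory accuracy) for binary outcomes, in tidyverse-native R.

## What it does, and for whom

Social epidemiologists studying how overlapping social positions jointly
shape an outcome — here, digital exclusion among people experiencing
homelessness and residents of urban communities in Brazil — need more than
one-variable-at-a-time regression. MAIHDA treats *intersectional strata*
(every cell of the cross-classification of gender × race/ethnicity ×
schooling × family income × public-health-system use; 2 × 3 × 4 × 4 × 2 =
192 cells) as the grouping level of a random-intercept logistic model and
asks two questions:

1. **How much inequality lies between strata?** Model 1 (null):
   logit Pr(y = 1) = β₀ + uₛ, uₛ ~ N(0, σᵤ²). The variance partition
   coefficient VPC = 100·σᵤ²/(σᵤ² + π²/3) gives the between-stratum share
   of latent variance; the AUC of stratum-based predictions gives the
   strata's discriminatory accuracy.
2. **Is it additive or intersectional?** Model 2 adds fixed main effects
   for every dimension. The proportional change in variance
   PCV = 100·(σ²ₙᵤₗₗ − σ²f)/σ²ₙᵤₗₗ says how much of the between-stratum
   variance the additive effects explain; each stratum's predicted
   probability decomposes exactly into an additive component
   (inverse-logit of the fixed effects) plus an interaction component.

The GLMM is estimated by maximum likelihood with adaptive Gauss–Hermite
quadrature (15 nodes by default), written from first principles and
cross-checked in the test suite against dense numerical integration and
`lme4::glmer(nAGQ = 15)`. Empirical-Bayes stratum predictions, parametric
simulation CIs, ranked caterpillar data, and extreme-strata tables complete
the workflow. Because the motivating survey's microdata are not deposited,
the package ships a seeded synthetic-cohort generator whose defaults
emulate that study's published marginals, odds ratios, and complete-case
exclusion rate.

## Worked example

```r
library(intermaihda)

cb  <- study_codebook()               # the five dimensions + outcome
cfg <- synthetic_config(seed = 1)     # study-scale defaults: n = 2652
cohort <- generate_population(cfg)

filt <- filter_complete_cases(cohort, cb)
filt$exclusions
#> <exclusion_report> 2652 raw, 236 excluded (8.9%), 2416 retained

m <- run_maihda(filt$cohort, cb, ci_reps = 1000, seed = 1)
m
#> <maihda> 2416 individuals in 124 of 192 possible strata
#>   VPC: null 16.9%, full 0.0% | PCV 100.0% | AUC: null 0.724, full 0.708

dplyr::select(tidy(m, exponentiate = TRUE), term, estimate, conf.low, conf.high)
#> # A tibble: 11 × 4
#>    term                            estimate conf.low conf.high
#>    <chr>                              <dbl>    <dbl>     <dbl>
#>  1 (Intercept)                        0.175    0.141     0.216
#>  2 genderWoman                        1.29     1.08      1.55
#>  3 raceWhite                          1.10     0.892     1.35
#>  4 raceOther                          1.75     1.15      2.68
#>  5 schoolingBasic education           1.84     1.45      2.32
#>  6 schoolingSecondary education       3.74     3.00      4.67
#>  7 schoolingHigher education          6.59     4.43      9.82
#>  8 income1-2 minimum wages            2.75     2.24      3.39
#>  9 income2-3 minimum wages            2.56     1.81      3.60
#> 10 incomeMore than 3 minimum wages    6.39     3.85     10.6
#> 11 sus_useNo                          1.09     0.798     1.49

extremes(m$predictions, k = 3)$lowest |>
  dplyr::select(stratum, gender, schooling, income, n_obs, p_null)
#> # A tibble: 3 × 6
#>   stratum gender schooling    income     n_obs p_null
#> 1 12111   Man    No schooling Low income   221   16.0
#> 2 21111   Woman  No schooling Low income    41   17.6
#> 3 11111   Man    No schooling Low income    63   19.1

autoplot(m)   # caterpillar of ranked null-model stratum probabilities
```

Reading the numbers: the null model puts 16.9% of latent variance between
strata (σᵤ² = 0.67) and the strata discriminate the outcome with AUC 0.72;
adding the five additive main effects absorbs essentially all of it
(full-model VPC ≈ 0, PCV ≈ 100%), so in this generated cohort — as in the
study it emulates — intersectional inequality is overwhelmingly additive:
schooling and income dominate (ORs up to ~6.6), and the least-reached
profile is men with no schooling and low income. Stratum IDs are digit
codes, one digit per dimension ("12111" = man, Black or Brown, no
schooling, low income, public-system user).

Design-stage helper: `cochran_sample_size(z = 1.96, epsilon = 0.05,
p = 0.5)` returns `385`, the classical minimum sample for a proportion at a
5% margin of error (finite-population correction via `N =`).

A thin command-line wrapper over the same functions lives at
`inst/scripts/maihda.R` (subcommands `simulate`, `analyze`, `describe`,
`samplesize`).

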