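---
title: "Intersectional MAIHDA for binary outcomes: models, assumptions, and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Intersectional MAIHDA for binary outcomes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## The problem and the model

Multilevel analysis of individual heterogeneity and discriminatory accuracy
(MAIHDA) treats *intersectional strata* — the cells of the full
cross-classification of social dimensions — as the grouping level of a
random-intercept model. `intermaihda` implements the two-model workflow for
a binary outcome. Its motivating application is digital exclusion among
highly vulnerable urban populations in Brazil: five dimensions — gender (2
analytic categories), race/ethnicity (3), schooling (4), family income in
minimum-wage bands (4), and use of the public health system, SUS (2) —
giving $2 \times 3 \times 4 \times 4 \times 2 = 192$ possible strata, with
the binary outcome being whether a participant sought COVID-19 information
on the internet.

Writing $y_{is}$ for the outcome of individual $i$ in stratum $s$,

* **Model 1 (null):**
  $\mathrm{logit}\,\Pr(y_{is}=1) = \beta_0 + u_s$, with
  $u_s \sim N(0, \sigma_u^2)$. The between-stratum variance captures *all*
  inequality between intersectional strata, additive and interactional.
* **Model 2 (full additive):** the same random intercept plus fixed main
  effects for every dimension. What remains of $\sigma_u^2$ after the main
  effects enter is attributable to intersectional interactions.

Derived statistics:

* **VPC** (variance partition coefficient), on the latent-response scale:
  $100\,\sigma_u^2/(\sigma_u^2 + \pi^2/3)$. We use the exact logistic
  residual $\pi^2/3 \approx 3.29$.
* **PCV** (proportional change in variance):
  $100\,(\sigma^2_{\text{null}} - \sigma^2_{\text{full}})/\sigma^2_{\text{null}}$;
  its complement indexes residual intersectional interaction.
* **AUC** of the stratum-level predictions, computed as the tie-corrected
  Mann–Whitney probability (stratum-constant scores make ties pervasive, so
  midranks are essential).
* **Per-stratum decomposition:** the *additive* probability
  $\mathrm{logit}^{-1}(x_s'\hat\beta)$ from model 2's fixed effects, the
  *total* probability $\mathrm{logit}^{-1}(x_s'\hat\beta + \hat u_s)$ with
  the empirical-Bayes (EB) stratum deviation, and their difference — the
  *interaction component* in percentage points. A parallel null-model
  probability ($\mathrm{logit}^{-1}(\hat\beta_0 + \hat u_s)$) is attached
  for ranking and caterpillar displays, which conventionally use the null
  model because it carries both additive and interactive structure.

## Estimation

The marginal likelihood integrates each stratum's random intercept against
its normal prior. We evaluate each one-dimensional integral by *adaptive
Gauss–Hermite quadrature*: a safeguarded Newton search finds the posterior
mode of $u_s$, the quadrature rule is centred there and scaled by the
curvature, and 15 nodes (the default; configurable) are summed on the log
scale. At 15 nodes the log-likelihood agrees with dense trapezoid
integration to well below $10^{-6}$ on small fixtures, and 15 vs 25 nodes
is indistinguishable at the same tolerance. At $\sigma_u^2 = 0$ the
integral collapses and the value equals the ordinary logistic
log-likelihood — a limit the test suite checks against `glm()`.

Optimization is quasi-Newton (`nlminb`) over $(\beta, \log\sigma_u)$. The
log parameterization keeps the variance positive; a lower bound far below
any plausible value handles the boundary, and a fit that lands there is
refitted as plain logistic regression and flagged `boundary`. Because
`nlminb` occasionally reports "false convergence" at a genuine optimum, the
convergence flag is confirmed with a central-difference score check rather
than trusted blindly. Fixed-effect standard errors come from the observed
information over $\beta$ at the estimated variance — the usual mixed-model
convention; on shared fixtures the whole fit (log-likelihood, coefficients,
variance) agrees with `lme4::glmer(nAGQ = 15)` to about $10^{-4}$.

EB stratum predictions are posterior modes (conditional modes, the
mixed-model convention; posterior means by quadrature are available via
`method = "mean"`), with a curvature-based posterior spread. Strata that
are possible but unobserved get a prior-only prediction of zero deviation
and spread $\sigma_u$, and are flagged so downstream tables can report them
as additive-only. Strata with all-0 or all-1 outcomes are retained:
shrinkage under the normal prior keeps their predictions finite.

Confidence intervals for stratum probabilities use parametric simulation
(the source study does not state its method): fixed effects are drawn from
their asymptotic normal, the stratum deviation from its EB posterior normal
approximation, `B = 1000` times by default, and the 2.5/97.5 percentiles
are taken on the probability scale. The draw is seeded and reproducible; a
`B` below 100 triggers a warning. Coverage of these intervals is checked by
simulation (about 95% observed for a mid-sized stratum at $n = 600$ over
200 replicates).

## Stratum IDs

Each stratum gets a digit-string ID, one digit per dimension, the digit
being the category's 1-based position in the codebook's analytic order
(gender: man = 1, woman = 2; race: White = 1, Black or Brown = 2,
other = 3; schooling from none = 1 to higher = 4; income from low = 1 to
more than 3 minimum wages = 4; SUS use: yes = 1, no = 2). So `"21321"` is a
woman, White, secondary education, 1–2 minimum wages, SUS user. Encoding
and decoding are exact inverses over all 192 cells. Reference categories
for model 2 follow the motivating study's convention: man, Black or Brown,
no schooling, low income, SUS user.

## The synthetic-data generator

No microdata are deposited for the motivating study, so the generator
emulates its published structure and is itself first-class, tested code:

* **Marginals** default to the study's descriptive table, renormalized over
  analytic categories (e.g. women 1001/2601 after dropping "No answer").
  The analytic sample's exact post-filter marginals are not published;
  these defaults are a documented approximation, not ground truth.
* **Additive effects** default to the natural logs of the study's fitted
  odds ratios (woman ln 1.49, higher education ln 5.59, >3 minimum wages
  ln 4.54, SUS non-use ln 0.92, ...), baseline log-odds ln 0.19.
* **Interaction variance** `sigma_int2` defaults to 0.033 — the residual
  between-stratum variance implied by the study's full-model VPC of 1%
  ($3.29 \times 0.01/0.99$). One deviation is drawn per *possible* cell
  (all 192, not just observed ones), so rare cells behave realistically;
  explicit per-cell interactions can be injected on top.
* **Missingness** defaults reproduce the study's complete-case exclusion in
  expectation: gender 51/2652 ("No answer"), income 176/2652 ("Did not
  know"), and an outcome rate of 0.0096 chosen so that independent
  per-variable missingness yields an expected 9.3% (247/2652) incomplete.
* Dimensions are sampled **independently** — the study publishes only
  marginals, no joint distribution. An optional log-linear `tilt` between
  schooling and income exists for stress tests and is off by default.

What passing tests on generated data do *not* show about real data: real
survey dimensions are correlated (schooling and income strongly so), real
missingness is not independent across variables, and real interaction
structure need not be exchangeable-normal across cells. The generator
checks the machinery under the model's own assumptions; it cannot validate
those assumptions.

## Problem sizes, numerical choices, and known limitations

The test suite exercises the pipeline at the study's own scale
($n \approx 2652$, 192 possible strata, typically 110–135 observed) and at
$n = 20000$ for asymptotic properties: under purely additive generation the
full-model VPC falls below 3% and the PCV exceeds 90%, reproducing the
mechanism behind the study's reported VPC collapse (24% to 1%, PCV 97%);
an injected +1 log-odds cell is recovered as the top interaction
component. Parameter recovery uses 100 replicates at $n = 5000$ with
interaction variance 0.3.

Two honest caveats from those simulations. First, with many sparse strata
the ML estimate of $\sigma_u^2$ is biased downward in finite samples (mean
0.24 against a true 0.30 at $n = 5000$; `glmer` behaves identically), so
Wald intervals for contrasts identified mostly *between* strata — gender,
in this design — run slightly anti-conservative: aggregate coverage across
all fixed effects is about 92%, but the gender term alone sits near 83%.
Second, at the study's own $n \approx 2400$ a small true interaction
variance (0.033) is frequently estimated at the boundary, giving
full-model VPC 0 and PCV 100 rather than 1% and 97%: detecting variance
that small simply needs more data than the design provides. Both phenomena
are properties of maximum likelihood at these sizes, not of this
implementation.

Other scope limits, by design: no survey weights, no imputation, no random
slopes or crossed random effects, no non-logit links, no Bayesian
estimation, and no collapsing of sparse strata (all observed strata are
analyzed regardless of size). Percent formatting in exported CSV tables is
half-up to one decimal, matching survey-table convention; JSON outputs keep
full precision.

## A minimal run

```{r, eval = FALSE}
library(intermaihda)

cb <- study_codebook()
cfg <- synthetic_config(seed = 1) # study-scale defaults, n = 2652
cohort <- generate_population(cfg)

filt <- filter_complete_cases(cohort, cb)
m <- run_maihda(filt$cohort, cb, ci_reps = 1000, seed = 1)

glance(m) # VPC, PCV, AUC, variance components
tidy(m, exponentiate = TRUE) # model-2 odds ratios
extremes(m$predictions, k = 5) # most and least advantaged strata
autoplot(m) # caterpillar of ranked null-model probabilities
```
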