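---
title: "Frailty as a mediator of age effects on stroke outcomes: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Frailty as a mediator of age effects on stroke outcomes: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(frailtymed)
```

## The scientific question

Older patients do worse after acute ischemic stroke, even when treated
with reperfusion therapy (intravenous thrombolysis and/or mechanical
thrombectomy). Part of that age effect may not be age itself but the
accumulated burden of health deficits — frailty — that rises with age.
`frailtymed` quantifies how much of the effect of age on binary 90-day
outcomes (disability-or-death, defined as modified Rankin Scale > 2, and
mortality) is transmitted through frailty, using regression-based causal
mediation analysis.

## The mediator: a deficit-accumulation frailty index

The frailty index (FI) is the fraction of assessed health deficits an
individual presents: each item in a deficit schema scores 1 when present
and 0 when absent, and the FI is the ratio of the deficit count to the
number of items actually assessed, so a person with 4 of 40 deficits has
FI = 0.1. Standard guidance asks for at least 30 items but prescribes no
particular item list; `validate_schema()` enforces the size-and-
uniqueness constraints and the packaged 31-item schema
(`default_deficit_schema()`) is a generic stand-in — comorbidities,
sensory/mobility deficits, and pre-stroke disability flags — that makes
the pipeline runnable. A real study substitutes its own schema, which is
what defines the index actually measured.

Two numerical choices are ours and are logged in every pipeline run:

* **Missing items** leave the denominator (the FI is
  present/assessed, the usual deficit-accumulation convention). When
  fewer than 80% of items were assessed (`min_assessed_fraction = 0.8`)
  the FI is set missing and the record falls to the complete-case
  filter. The threshold is a data-quality guard, not an estimate; any
  value in [0.7, 0.9] would be defensible.
* The FI is treated **strictly as a continuous variable** downstream.
  No frailty categories or cut-points exist anywhere in the package.

## The structural models

With exposure $A$ (age in years, unscaled — effects are per 1-year
increment), mediator $M$ (the FI), outcome $Y$ (binary), and covariates
$C$ (sex, race, admission NIHSS as a continuous score, and smoking
status; the disjunctive-cause adjustment set — other comorbidities are
already inside the FI and are not adjusted for), the two fitted models
are

$$E[M \mid a, c] = \beta_0 + \beta_1 a + \beta_2' c, \qquad
  \operatorname{logit} P(Y = 1 \mid a, m, c)
  = \theta_0 + \theta_1 a + \theta_2 m + \theta_3 a m + \theta_4' c.$$

$\beta_1$ is path *a* of the mediation diagram, $\theta_2$ path *b*,
$\theta_1$ path *c* (the direct path); $\theta_3$ is the
exposure–mediator interaction, zero when disabled. The mediator model is
ordinary least squares; the outcome model is maximum-likelihood
logistic regression (IRLS, deviance tolerance $10^{-8}$, 100-iteration
cap). Separation — fitted probabilities pinned at 0/1 together with
diverging coefficients — is an explicit error, not a fallback to
penalised fitting: the reported method is plain ML, so a dataset that
cannot support it should say so. Reference coding is sex = female,
race = black, smoking = never; the choice only relabels coefficients
and is recorded in the output.

## Natural effects and the proportion mediated

For a change of exposure from $a^*$ to $a$, under the rare-outcome
approximation, the natural-effect log odds ratios are closed forms in
the coefficients:

$$\log OR^{NDE} = \left[\theta_1 + \theta_3\left(\beta_0 + \beta_1 a^*
  + \beta_2' c + \theta_2 \sigma^2\right)\right](a - a^*)
  + \tfrac{1}{2} \theta_3^2 \sigma^2 (a^2 - a^{*2}),$$

$$\log OR^{NIE} = (\theta_2 \beta_1 + \theta_3 \beta_1 a)(a - a^*),
  \qquad \log OR^{TE} = \log OR^{NDE} + \log OR^{NIE},$$

where $\sigma^2$ is the mediator residual variance. Without the
interaction these collapse to $\theta_1 (a - a^*)$ and
$\theta_2 \beta_1 (a - a^*)$ and do not depend on the covariate
conditioning vector $c$. The total-effect decomposition holds as an
algebraic identity of the estimator, and the test suite asserts it to
machine precision on every fit.

The proportion mediated is computed on the odds-ratio scale,
$PM = OR^{NDE}(OR^{NIE} - 1)\,/\,(OR^{NDE} OR^{NIE} - 1)$, not as a
naive ratio of log odds ratios. The reported PM interval is truncated
to [0, 1] (it is a proportion); the raw interval is kept in the
machine-readable output.

**Defaults that matter.** The exposure contrast is $a^* =$ sample mean
age and $a = a^* + 1$ year, so odds ratios read "per additional year of
age"; any contrast (e.g. a decade) can be requested. The conditioning
vector defaults to covariate sample means and only enters with the
interaction. Both defaults are printed with every report.

## Uncertainty

Delta-method standard errors propagate the two coefficient covariance
matrices — stacked block-diagonally, i.e. the two fits treated as
independent, with $\sigma^2$ held fixed — through analytic gradients of
the log-OR expressions. The joint 2×2 covariance of
$(\log OR^{NDE}, \log OR^{NIE})$ is retained for PM inference, whose
gradient is also analytic (the test suite checks it against finite
differences). Both simplifications are standard for this estimator; the
participant-level bootstrap (`bootstrap_mediation()`, percentile
intervals, failed resamples counted and >10% failures an error) is the
package's own check on them, and the validation suite requires
delta-method and 2000-replicate bootstrap endpoints to agree within 10%
of the interval width on a fixed synthetic cohort of n = 3000.

## The rare-outcome approximation, stated honestly

The closed forms treat odds ratios as risk ratios, which is accurate
when the outcome is rare. The validation suite demonstrates, against a
counterfactual Monte-Carlo oracle (`true_effects()`, independent
mediator draws per counterfactual arm, $10^6$ draws), that at
prevalence ≤ 5% formula and oracle agree within 3 Monte-Carlo standard
errors, and the approximation error is *visible* at 40% prevalence —
which is exactly the regime of the composite stroke outcome (~47%).
`mediate_age_frailty()` therefore raises a classed warning whenever
prevalence exceeds 10% rather than silently proceeding. The estimator
remains internally consistent (it recovers its own estimand — the
formula evaluated at the true coefficients — without bias at any
prevalence); what degrades is the causal reading of the odds ratios as
risk-ratio-like natural effects.

## Interaction testing

`test_interaction()` reports three pieces of evidence: the Wald test of
$\theta_3$, the likelihood-ratio test of the nested model pair, and the
shift in $\log OR^{NDE}$ / $\log OR^{NIE}$ when the interaction is
added. Under a null interaction the Wald test holds its 5% size in the
validation suite (1000 simulated cohorts).

## Multicollinearity and descriptive statistics

`vif()` computes $1/(1 - R_j^2)$ per predictor; the pipeline warns
above 3. The baseline table follows the usual routing: Shapiro–Wilk at
0.05 decides mean (SD) vs median (Q1, Q3) — type-7 linear-interpolation
quantiles throughout — and, for group comparisons, Welch's
unequal-variance t vs the Wilcoxon rank-sum test (tie-corrected normal
approximation); contingency tables use chi-square without continuity
correction when every expected count is ≥ 5 and Fisher's exact test
otherwise (Fisher on tables beyond 2×2 is refused with advice to
collapse). Shapiro–Wilk is defined up to n = 5000; larger samples are
thinned to a deterministic evenly-spaced subsample of the sorted
values. Group-comparison p-values are off by default: a single-cohort
baseline table reports no tests.

## The synthetic-cohort generator

No patient-level data ship with the package, so `sim_params()` /
`simulate_cohort()` define the study conditions the validation runs
under: age truncated-normal (mean 67.7, SD 13.1, floor 19 years), 56.5%
male, 89% white, smoking never/former/current at 51.7/19.2/29.1%,
NIHSS as a rounded lognormal with median 12 and IQR ≈ 7–18, an FI
rising 0.002 units per year of age around a mean near 0.10, and a
logistic outcome whose intercept is calibrated by bisection (on a large
fixed internal draw, so it is deterministic) to the scenario
prevalence: 46.9% for the composite outcome, 18.5% for mortality. The
default effect sizes — direct OR ≈ 1.02/year, indirect OR ≈ 1.01/year,
hence PM near a third — match the magnitudes this literature reports
and are illustrative, not a reproduction of any cohort.

Two mediator modes exist. `gaussian` draws the FI from the linear model
and clips to [0, 1]; the clip rate is attached to the cohort and warns
above 5%, because clipping distorts the generative truth (the MC oracle
deliberately uses the *unclipped* structural model). `deficit_level`
draws 31 age-dependent Bernoulli deficits whose logit slope is
calibrated so the induced FI–age slope matches $\beta_1$; there the FI
is an exact deficit ratio and internally consistent with
`compute_fi()`. Covariates are drawn independently (only marginals are
emulated), mRS is assigned consistently with the drawn binary outcome,
and every cohort passes `validate_cohort()` unchanged.

What the generator does **not** emulate — and hence what passing tests
do not show about real data: the joint covariate distribution of any
real cohort, informative missingness (simulated cohorts are complete),
treatment-modality structure, and any deviation of real frailty from
the linear-in-age Gaussian (or calibrated-Bernoulli) mediator model.

## Validation problem sizes

The validation suite runs at sizes chosen to make Monte-Carlo error
bars meaningful while keeping the suite quick to run routinely:
estimator-vs-oracle agreement at $10^6$ oracle draws; bias of
$\log OR^{NDE}$ and $\log OR^{NIE}$ over 500 replicates of n = 5000
(pass: |bias| < 3 MC SEs); 95% CI coverage for $\log OR^{NIE}$ over
1000 replicates of n = 2000 (pass: 93–97%); the bootstrap
cross-validation at n = 3000, B = 2000. The rare-outcome recovery
scenario uses 8% mortality with a mediator mean of 0.30, where clipping
is absent by construction — recovery there isolates estimator
behaviour from generator truncation.

## Known limitations

* The natural-effect formulas are rare-outcome approximations; for the
  ~47% composite outcome the odds ratios remain well-defined estimates
  of the formula estimands but overstate risk-ratio-scale effects.
  Odds-ratio noncollapsibility is inherited from the estimator.
* The delta method ignores uncertainty in $\sigma^2$ and the
  cross-model covariance; the bootstrap is provided precisely to check
  this in any given dataset.
* Complete-case analysis throughout; no imputation is implemented, by
  design. The exclusion report makes the cost visible.
* One mediator, one exposure, binary outcomes; no
  exposure-induced confounding of the mediator-outcome path, no
  sensitivity analysis for unmeasured confounding.
```{r session}
sessionInfo()
```
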