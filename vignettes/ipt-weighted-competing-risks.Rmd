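---
title: "IPT-weighted competing-risks analysis with wcr"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{IPT-weighted competing-risks analysis with wcr}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(wcr)
```

## The problem

Long-term treatment complications -- say, urinary adverse events after
prostate cancer therapy in an elderly cohort -- are observed under two
obstacles at once.  First, death is a *competing event*: a subject who dies
can never go on to experience the complication, so censoring deaths in a
Kaplan-Meier (KM) analysis overstates the cumulative incidence of the
complication.  Second, treatment is not randomized: sicker or older
patients end up in different arms, so crude between-arm contrasts are
*confounded*.  `wcr` addresses both at once: the Aalen-Johansen estimator
and cause-specific Cox models handle the competing event, and stabilized
inverse-probability-of-treatment (IPT) weights handle the measured
confounding.

## Estimands and estimators

Let $T$ be the follow-up time in days and $D \in \{0, 1, 2\}$ the event
code (0 censored, 1 event of interest, 2 competing event).  With distinct
event times $t_j$, $d_j$ events and $n_j$ at risk, the KM estimator of
event-free survival is

$$\hat S(t) = \prod_{t_j \le t}\Bigl(1 - \frac{d_j}{n_j}\Bigr).$$

The cumulative incidence function (CIF) of cause $k$ is
$I_k(t) = P(T \le t, D = k) = \int_0^t \lambda_k(x)\, S(x)\, dx$, with
$\lambda_k$ the cause-specific hazard.  Its nonparametric (Aalen-Johansen)
estimate discretizes the integral as

$$\hat I_k(t) = \sum_{t_j \le t} \frac{d_{kj}}{n_j}\, \hat S(t_j^-),$$

where $\hat S(t_j^-)$ is the left-limit of the *all-cause* KM curve.  The
"naive KM CIF" $1 - \hat S_k(t)$, obtained by censoring competing events,
replaces $\hat S(t_j^-)$ by the larger cause-$k$-only survival, so it can
never fall below $\hat I_k(t)$; the package asserts this dominance on every
report it renders.  At every event time the estimates obey
$\sum_k \hat I_k(t) + \hat S(t) = 1$ exactly, which the test suite checks to
$10^{-10}$.

Under IPT weighting every count is replaced by a weight sum.  Weights are
*stabilized*: a subject observed in arm $a$ with covariates $X$ receives
$w = \Pr(A = a) / \Pr(A = a \mid X)$, with the denominator from a single
multinomial-logistic propensity model (or, for case/control designs with a
second treatment stage, the product of the two stabilized stages).
Stabilization keeps the mean weight near 1.  Extreme weights are truncated
at a percentile of the raw weights -- capping by default, deletion
optionally; both are recorded in the weight set's provenance.

Cause-specific hazard ratios come from a Cox partial likelihood in which
competing events are censored at their event time.  With weights the
model-based variance is invalid, so the package always reports the robust
(sandwich) variance with subjects as independent units.

## Tunable parameters and defaults

* **Horizon** -- reporting time for CIFs; default 3650 days (the package's
  10-year convention).  All internal computation is in days at full
  precision; percentages are rounded only at render time.
* **Truncation percentile** -- default 99, cap mode.  The cutoff is the
  linearly interpolated percentile (R's type-7 quantile) of the *raw*
  weights, which makes capping idempotent.  Percentiles at or below 50 are
  refused.  The conflation in common practice between "capping" and
  "deleting" extreme weights is resolved by offering both modes, cap being
  the default because it preserves the sample.
* **Ties** -- Breslow by default (the convention of the SAS procedure most
  weighted analyses use); Efron by flag.  Robust-variance score residuals
  use Breslow-style hazard increments in both cases, which coincide
  whenever event times are untied -- the simulator produces continuous
  times, so ties only arise in hand-built fixtures.
* **Probability floor** -- denominator propensities below `1e-6` flag the
  subject in the weight set rather than failing silently.
* **Convergence** -- Newton-Raphson from $\beta = 0$, step-halving on
  likelihood decrease, stopping at a maximal update below $10^{-9}$ or a
  relative log-likelihood change below $10^{-12}$; coefficients beyond
  $|\beta| > 20$ are declared monotone-likelihood failures and raise an
  error suggesting penalization, as does non-convergence within 100
  iterations.

## The synthetic cohort generator

Because registry claims data of this kind are access-restricted, the
package ships a simulator that reproduces the *structure* of such a cohort
rather than any particular dataset: a control arm plus six treatment arms
(external beam radiotherapy, brachytherapy, their combination, radical
prostatectomy, prostatectomy + radiotherapy, cryotherapy), age with a
minimum of 66 years, a three-level comorbidity score, a baseline-event
history indicator, a low-socioeconomic-status indicator, and race.
Assignment is multinomial-logistic on these covariates; the two competing
causes have exponential cause-specific hazards of proportional-hazards form
with known per-arm hazard ratios, so the truth is available in closed form:

$$I_1(t) = \frac{\lambda_1}{\lambda_1 + \lambda_2}
  \bigl(1 - e^{-(\lambda_1+\lambda_2)t}\bigr).$$

Design choices worth stating explicitly:

* The default true cause-1 hazard ratios (1.2, 1.6, 2.2, 2.8, 3.7, 1.75
  versus control) echo the magnitudes reported in the motivating literature
  so that demonstration reports look qualitatively familiar; they are
  simulation parameters, not reproduction targets.  The competing-cause
  hazard ratios are all below 1, making the control arm the highest-mortality
  arm -- the counterintuitive pattern seen in screening-selected cohorts.
* Healthier subjects (younger, lower comorbidity, no baseline event, higher
  socioeconomic status) are strongly steered toward the surgical arms.  The
  coefficients were calibrated once so that, at $n = 20{,}000$, the cohort
  shows material baseline imbalance (maximum standardized mean difference
  above 0.25), the crude unweighted hazard ratios for the surgical arms are
  biased by more than 15%, and a correctly specified propensity model
  restores balance (maximum weighted SMD below 0.1, mean stabilized weight
  within 0.02 of 1) and recovers every true hazard ratio within 10%.
  Stronger confounding makes p99 weight capping itself re-introduce
  imbalance, which is why the calibration is a compromise rather than "as
  confounded as possible".
* `ses_low` and `race` affect assignment but not the hazards.  They mimic
  the common situation of a propensity model richer than the outcome
  adjustment set; the IPT-weighted Cox model here adjusts for `z_age`,
  `comorbidity` and `baseline_event` only.
* Arm shares are far more balanced than in the motivating registry (the
  smallest arm is ~7% rather than ~0.6%) and event rates are higher; at
  simulation scale every arm then carries enough events for informative
  hazard-ratio recovery.
* Event times are continuous, so cross-cause ties never occur by
  construction; tie handling is exercised by hand-built fixtures instead.
  Same-day ties in real data are resolved by the recorded event code.
* The independent exponential censoring rate (default `8e-5`/day) has no
  empirical anchor; it is a free parameter chosen to censor a modest
  fraction of follow-up.
* A Weibull shape option exists for sensitivity exploration, but all
  validation uses the unit-shape (constant-hazard) configuration, where the
  truth is closed-form.

What passing the validation suite shows -- and what it does not: the
machinery is correct under exponential hazards, a correctly specified
propensity model, and independent censoring.  Real cohorts offer none of
these guarantees; in particular the weights can only remove *measured*
confounding, and the simulator contains no unmeasured confounder, no
informative censoring, and no model misspecification.

## Uncertainty

Greenwood pointwise variances accompany unweighted KM curves.  For any
weighted statistic the package deliberately provides only the subject-level
percentile bootstrap (`bootstrap_ci()`), re-estimating the weights inside
every resample; resamples without events of the target cause are dropped
and counted.  The validation suite checks, over 300 simulated cohorts of
$n = 1000$ with 200 replicates each, that the 95% interval for the
IPT-weighted 10-year CIF covers the closed-form truth in $95 \pm 3$% of
cohorts.  (The coverage target is the treated-arm CIF standardized to the
marginal confounder distribution -- a finite mixture of closed forms, since
the hazard-relevant confounders in that configuration are discrete.)

## Worked example

```{r example, eval = FALSE}
sim <- generate_cohort(sim_config(n = 20000, seed = 1))
rep <- run_analysis(sim$cohort,
                    adjust = c("z_age", "comorbidity", "baseline_event"),
                    verbose = FALSE)
render_report(rep, "text")
```

The four CIF rows per arm separate the two corrections: moving from the KM
rows to the competing-risks (CR) rows removes the upward bias from
censoring deaths; moving from the unweighted to the IPT-weighted columns
removes the confounding in the between-arm comparison.  The dominance
invariant (CR $\le$ KM within every arm and weighting) is asserted at
render time.

## Problem sizes used in validation

The shipped validation suite uses $n = 50{,}000$ for the closed-form
consistency check, 1000 fuzzed mini-cohorts (at most 12 subjects each)
against a day-by-day brute-force enumeration oracle, $n = 20{,}000$ for the
confounding-removal study, and $300 \times 200$ bootstrap replicates for
coverage -- sizes chosen so the whole suite completes on a single CPU in
well under half an hour while keeping Monte-Carlo error far from the
acceptance margins.

## Known limitations

* Cause-specific hazards only; subdistribution (Fine-Gray) regression is
  out of scope, as are time-varying treatments and weights.
* No left truncation / delayed entry.
* Greenwood variances for *weighted* curves are not offered at all rather
  than offered incorrectly; the bootstrap is the supported route.
* The two-stage weight construction assumes the stage-2 model is fitted on
  exactly the case subset, with stabilization by arm proportions among
  cases.
* The truncation percentile is computed over all subjects by default;
  per-arm truncation can be emulated by truncating arm subsets separately.
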