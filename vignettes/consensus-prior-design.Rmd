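---
title: "Consensus prior elicitation and Bayesian design for a small two-arm trial"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Consensus prior elicitation and Bayesian design for a small two-arm trial}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(crmobayes)
```

## The problem

Chronic nonbacterial osteomyelitis (CNO/CRMO) is a rare paediatric bone
disease. A randomised comparison of adalimumab (a TNF inhibitor) and
pamidronate (a bisphosphonate) can realistically recruit only about 20
patients per arm, far too few for a conventionally powered trial. The
design this package implements instead treats clinicians' accumulated
prescribing experience as data: expert opinion is elicited and encoded
as a prior distribution, the trial updates that prior, and decisions
are based on posterior probabilities. The package covers the whole
chain — elicitation, aggregation, prior fitting and calibration, exact
conjugate updating, and simulation of the design's frequency
properties.

## Outcome model and opinion model

The endpoint is the week-26 change from baseline in pain score on a
100 mm visual analogue scale; negative change means improvement.
Outcomes are Gaussian with a common variance `1/tau` across arms, with
no baseline adjustment and no truncation to the 0–100 mm range — a
pragmatic model that is adequate while scores stay away from the scale
boundaries. The unknowns are `mu_P` (average pamidronate change),
`delta = mu_A - mu_P` (treatment effect; negative favours adalimumab)
and the precision `tau`.

Opinion about the unknowns is conjugate Normal-Gamma
(`ng_belief()`): `tau ~ Gamma(a0, b0)` and, given `tau`,
`(mu_P, delta) ~ N((mu_P0, delta0), R/tau)`. Two consequences are used
everywhere and are exact, never approximated by normals:

* any contrast `c'(mu_P, delta)` is location–scale Student-t with
  `2 a0` degrees of freedom and scale `sqrt((b0/a0) c'Rc)`
  (`ng_marginal()`);
* a single future patient's change is Student-t with scale
  `sqrt((b0/a0)(1 + c'Rc))` (`ng_predictive()`) — sampling noise plus
  parameter uncertainty, which is precisely the quantity experts are
  asked about.

The t-tail choice matters at the sample sizes involved: with `a0 = 2`
the marginals have 4 degrees of freedom, and the implied prior
probability that `delta` exceeds zero differs visibly from a Gaussian
model with the same 90% interval.

## Elicitation and aggregation

Experts answer five questions per arm: the percent chance that a
typical patient, presenting at baseline with a 60 mm score, records a
26-week score below a stated threshold. Thresholds decrease down the
questionnaire, so valid answers are non-increasing; an optional
interval-weights table (a belief histogram over score ranges) provides
an internal consistency check (`histogram_check()`, scored by total
variation distance over the stated bins).

The exact thresholds of the original questionnaire were not published
with the main analysis; the package ships placeholder thresholds
`{60, 30, 20, 10, 5}` mm as configuration, clearly labelled as
placeholders. Because of this, hyperparameters fitted from the panel's
raw answers are *not* presented as a reproduction of the published
prior; the published prior is reconstructed separately by calibration
(below).

`fit_predictive_from_answers()` converts each stated probability to a
standard-t quantile and regresses thresholds on those quantiles by
ordinary least squares. This quantile-transform fit was chosen because
it is deterministic, closed-form, and exact whenever the answers lie on
a t CDF of the fitting degrees of freedom; on inconsistent answers it
minimises the threshold-scale residual sum of squares. Answers of
exactly 0% or 100% have infinite quantiles and are dropped from the fit
(logged); real panels do produce such answers.

Consensus is formed on the *answer* scale — the arithmetic mean of the
experts' probabilities per question (`consensus_answers()`), with a
median option — not by pooling fitted distributions. This mirrors
behavioural aggregation practice: the group adopts the mean answers as
its consensus position after discussion. Experts are weighted
uniformly; no weighting information is available.

`fit_belief_from_panel()` decomposes the two fitted predictive scales
into hyperparameters given a sampling variance `b0/a0` and a
between-arm opinion correlation `rho`. The decomposition rule is a
package design choice (no published rule exists): per-arm parameter
uncertainty is whatever predictive spread exceeds the sampling
variance, and `rho` (default 0.99) controls how much of it cancels in
`delta`. A high default is the only way a treatment-effect prior can be
far narrower than either arm marginal while per-arm predictive spreads
stay wide, which is the qualitative structure of the published
consensus prior.

## Calibrating the published consensus prior

The published analysis reports summaries of its consensus prior but not
the fitted hyperparameters. `calibrate_from_summaries()` inverts the
summaries exactly:

* `a0` is fixed at 2 (marginals with 4 df). This value is jointly
  consistent with the published 90% interval for `delta` and the
  published probability that `delta > 0` to within half a percent; the
  latter is deliberately *held out* of the calibration as a check.
* `b0 = 4.6 * qgamma(0.25, 2, rate = 1) = 4.42` mm² from "4.6 is the
  75th percentile of the outcome-variance prior". The variance summary
  is read on the variance scale (mm²), not as a standard deviation:
  only the mm² reading reproduces the posterior interval widths under
  the large-variance hypothetical dataset. A `variance_units = "sd"`
  flag provides the alternative reading.
* `mu_P0 = -32.3`, `delta0 = 2.3` from the prior modes (t marginals are
  symmetric, so mode = location).
* the `delta` diagonal of `R` from the half-width of the equal-tailed
  90% interval (−6.9, 11.5) mm; the `mu_P` diagonal from the 84.2%
  predictive chance that a pamidronate patient improves at all.
* `R` is diagonal: nothing in the published summaries identifies the
  prior correlation of `mu_P` and `delta`, and all downstream
  reproductions succeed with zero.

Calibration is idempotent (re-calibrating from the extracted summaries
of its output returns the same hyperparameters), and all credible
intervals are equal-tailed — for these symmetric t marginals the
highest-density interval coincides anyway.

## Updating and the decision rule

`ng_update()` performs exact conjugate updating from two-arm summary
statistics (per-arm n and mean change, pooled variance with denominator
`n_P + n_A - 2`). The sufficient statistics are converted to design
cross-products and the standard Normal-Gamma recursions applied; solves
use the symmetric Cholesky factorisation and the posterior rate uses
the quadratic-form residual identity rather than explicit residuals,
avoiding cancellation. Updating with summaries is algebraically
identical to updating with any patient-level data sharing those
statistics, and sequential updates compose exactly — both are tested
against an independent patient-level oracle.

The clinically relevant margin is multiplicative on the change scale:
arm X beats arm Y relevantly when `mu_X <= (1 + margin) * mu_Y` with
`mu_X < 0`, margin 0.30. This parameterisation is forced by the
simulation scenario grid, whose superior/inferior mean pairs satisfy
`mu_inferior = mu_superior / 1.3`. The rule declares a difference when
the posterior probability that *either* arm is relevantly superior
exceeds 0.2; the two events are disjoint for any positive margin
(asserted on the Monte-Carlo draws), so the union equals the sum. A
`combine = "max"` variant thresholds each arm's probability separately;
under the null the two differ negligibly. Posterior probabilities are
computed by direct Monte-Carlo from the closed-form joint (default
10,000 draws) — with full conjugacy no MCMC sampler is needed, and the
Monte-Carlo standard error is reported.

## Operating characteristics

`run_operating_characteristics()` simulates trials of 20 patients per
arm under a fixed truth `(mu_P, mu_A, sigma)`, updates the consensus
prior with each simulated summary, applies the rule, and reports the
declared proportion with its binomial standard error. The shipped
scenario grid pairs three plausible pamidronate truths (−32.3, −40,
−26 mm) with no-difference and boundary-difference adalimumab means and
standard deviations 7.5–11.5 mm. Those sigma values sit far in the tail
of the calibrated variance prior; they are used verbatim as stated, and
the resulting prior-data conflict is part of what the simulation
measures. Default sizes are 1000 trials by 10,000 draws; each trial
runs on its own substream derived from the master seed
(`substream_seed()`), so any single trial can be regenerated
independently and results are bit-for-bit reproducible. Because each
trial's posterior probability is itself estimated, trials landing
within 3 Monte-Carlo standard errors of the 0.2 threshold can be
misclassified; their fraction is reported as `boundary_fraction` so
users can judge whether more draws are warranted.

## Synthetic data

`generate_expert_panel()` emulates the structure the elicitation fit
assumes: each synthetic expert perturbs the true predictive location
(Gaussian noise proportional to the predictive scale) and log-scale,
evaluates the perturbed CDF at the thresholds, rounds to a 5% grid
(real panels answer predominantly in multiples of 5), clamps to
[0, 100] and restores monotonicity by a pool-adjacent-violators
adjustment so generated panels are always valid. It does *not* model
expert psychology — anchoring, overconfidence, herding — so parameter
recovery under the generator shows the fitting machinery is correct,
not that real elicitations are unbiased. `generate_patient_data()` and
`summarize_patients()` provide Gaussian patient-level outcomes and
their sufficient-statistic reduction for testing the updating path.

## Numerical choices and degenerate inputs

* Zero-scale `scaled_t` objects are point masses with step-function
  CDFs; zero-width elicitation intervals and all-equal answers are
  errors, not silently degenerate fits.
* A positive semi-definite `R` (certainty about a mean combination) is
  accepted only behind an explicit `degenerate` flag and cannot be
  updated.
* Trials with fewer than 3 patients carry no pooled variance; the
  update then uses only the mean information.
* Floating-point output is serialized with 17 significant digits, which
  round-trips doubles exactly; human-readable reports round to 0.1 mm.

## Problem sizes used in the test suite

The packaged tests exercise the full published-scale simulation (six
scenarios, 1000 trials, 10,000 draws — about half a minute) and use
reduced sizes (tens to hundreds of trials) for property checks where
the published scale adds nothing; Monte-Carlo assertions state their
tolerance as multiples of the relevant standard error throughout.

## Known limitations

* Only two arms, a common outcome variance, and no covariate
  adjustment or score truncation — faithful to the planned trial's
  pragmatic model, and not extensible without changing the conjugate
  structure.
* The panel-fit variance decomposition (`sampling_variance`, `rho`) is
  under-identified by five threshold answers per arm; it is
  configuration, and its defaults are conventions, not estimates.
* Published summaries are printed to 1 decimal place, so quantities
  reconstructed from them inherit rounding error of a few hundredths
  of a millimetre; simulation-based published values carry their own
  Monte-Carlo error of order 0.01 on a proportion.
* No interim analyses or stopping rules: the rule is evaluated once,
  at the final analysis.
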