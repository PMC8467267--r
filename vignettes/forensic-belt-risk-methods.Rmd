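---
title: "Quantifying seat belt non-use in crash litigation: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantifying seat belt non-use in crash litigation: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(crashcausal)
```

## The problem

When a crash injury claim is defended on contributory negligence — "the
claimant was not wearing their seat belt" — the question a court actually
needs answered is counterfactual: *given this crash (its delta V, direction
of force, airbag deployment, vehicle), how much more likely was this injury
or death because the occupant was unbelted?* A general maxim ("seat belts
save lives") answers nothing case-specific; the answer has to come from
population data on comparable crashes, analysed with the legal threshold in
mind. The civil standard of proof — "more probable than not" — translates
into quantitative epidemiology: non-use can only be deemed the cause of the
injury if more than 50% of the unbelted risk is attributable to non-use,
i.e. an attributable risk (AR) above 50%, equivalently a relative risk (RR)
above 2.0.

`crashcausal` implements that analysis end to end: cohort construction from
occupant-level records of a stratified multistage crash sample, a
survey-weighted logistic model of outcome risk over delta V, and the
two-stage decision calculus that converts fitted risks into a legal
apportionment.

## The decision calculus

With `p1` the outcome risk for the unbelted occupant at the case profile and
`p0` the counterfactual belted risk:

* relative risk `RR = p1 / p0`;
* attributable risk `AR = (RR - 1) / RR x 100% = (p1 - p0) / p1 x 100%`;
* absolute risk difference `p1 - p0`.

Stage one asks whether there is statistically reliable evidence that
`AR > 50%` (strictly: equality fails, because "more probable than not" is a
strict majority). Stage two, reached only if stage one passes, quantifies
the claimant's contributory share. Under the default
*contributory-negligence* framing that share is the **absolute** risk
difference, not the attributable fraction: the population the claimant
belongs to is everyone in the crash, survivors included, so an exposure that
moves a rare risk from 1 to 10 per ten million contributes 9 per ten
million, however large the ratio looks. The *product-defect* framing
(`framing = "product_defect"`, e.g. a belt latch that failed in a rollover)
has no intervening crash risk between defect and outcome — cause and effect
are proximate — and there the attributable fraction itself is the
apportionment.

Two significance assessments are computed. The governing default is a Wald
test of the probability-scale difference by the delta method. Because both
risks come from one fitted model and share coefficients, the variance of
the difference includes their covariance,
`var(p1 - p0) = se1^2 + se0^2 - 2 cov(p1, p0)`; omitting the covariance
(as when two independent published risks are compared) is available as the
`cov_p = 0` default of `assess_significance()`. The CI-overlap heuristic —
significant only when the two 95% intervals are disjoint — is reported
alongside, labelled conservative, because it is how the comparison is
commonly illustrated in medicolegal reports. When the two methods disagree,
both verdicts are in the report.

Open choices resolved here: the AR > 50% gate is assessed at the **point
estimate**, with the interval printed beside it, because the legal standard
addresses the probability itself, not its lower confidence bound; and an
apparently protective non-use (RR < 1, as can genuinely occur in very
severe frontal crashes) is surfaced with a flag rather than truncated at 1.

## The risk model

The outcome is binary (death within 30 days, or a maximum known AIS at or
above a cut point). The model is logistic in delta V with a belt-non-use
indicator, optionally airbag deployment, vehicle body type, model year, a
quadratic delta V term, and a delta V x belt interaction (default **on**:
belted and unbelted risk curves observed in severe frontal crashes cross,
which a main-effects model cannot represent; with the interaction present
the main-effects fit is simply nested).

Crash samples of this kind are stratified multistage probability samples:
severe (tow-away, police-reported) crashes are oversampled, and each record
carries a national inflation weight plus stratum and PSU (primary sampling
unit) labels. Two consequences drive the estimation:

1. **Point estimates** maximise the weight-weighted binomial log-likelihood
   (pseudo-maximum-likelihood). Weights are sampling weights, never
   frequency weights: duplicating every record at half weight changes
   nothing.
2. **Uncertainty** comes from the Taylor-linearized (sandwich) estimator:
   weighted score contributions are totalled per PSU, and their between-PSU
   variance is pooled within strata under the with-replacement
   approximation, with the `n_h/(n_h - 1)` small-sample factor. A stratum
   with one PSU cannot contribute a between-PSU variance; its total is
   centred at the grand mean of PSU totals and a warning is raised.

Numerics: Newton-Raphson with an intercept warm start; convergence when the
maximum coefficient change relative to `max(|beta|, 0.01)` falls below 1e-8
(the 0.01 floor keeps genuinely zero coefficients from stalling the
criterion at machine noise), at most 100 iterations; a 1e-8 ridge on a
singular information matrix, with a warning; divergence beyond |beta| = 100
or fitted probabilities at numerical 0/1 is reported as complete separation
naming the suspect term. Confidence intervals for predicted risks are
formed on the logit scale (normal quantile 1.959964) and transformed, so
they always lie in [0, 1] and are order-preserving.

## Cohort construction

`cohort_spec()` declares the case-matching rules; the defaults reproduce a
driver-side frontal cohort: drivers only, PDOF inside the closed 9-to-11
o'clock arc (both endpoints included — "from 9 to 11" reads as inclusive;
whether the upper bound should extend to 11:59 is surfaced in the report
rather than silently decided), rollovers excluded, belt and airbag status
known, years 2001-2015. Rules apply in a fixed declared order and each
excluded record is charged to the first rule it fails, so the ledger
conserves counts exactly (`n_in = n_out + sum(removed)`); permuting the
order can move counts between rules but never changes the cohort. Records
with missing delta V pass the filter and are instead excluded (and counted)
at fitting time: cohort membership and model-variable knownness are
different questions. PDOF is held internally in degrees [0, 360), clockwise
from 12 o'clock; clock notation is accepted everywhere.

"Single frontal collision" is operationalised as PDOF-in-arc plus
no-rollover; multi-event crashes are not separately excluded because the
interchange format carries no reliable event-count field.

## The synthetic generator

Real national crash-sample microdata cannot ship with a package, so every
stage is validated against `generator_params()` populations with a known
mechanism:

* **Delta V**: gamma, parameterised by mode (12 mph) and spread (sd 12 mph).
  This reproduces the qualitative shape of the national frontal-crash
  severity distribution — unimodal, right-skewed, with about 1% of crashes
  at or beyond 56 mph, which places a 56 mph crash in the upper percentile
  of frontal severity.
* **Mechanism**: death risk is exactly
  `plogis(-7.0 + 0.143 dv + 1.87 unbelted - 0.3 airbag - 0.04 dv x unbelted)`.
  These defaults were fixed once, before any calibration experiment, to
  give mid-60s-to-mid-70s percent death risk at 56 mph for both belt states
  and curves crossing near 47 mph — the pattern reported for very severe
  frontal crashes, usually attributed to compartment intrusion and airbag
  compensation. At low-to-moderate delta V non-use is strongly harmful.
* **Composition**: 23% unbelted and 25% airbag deployment (taken from the
  weighted cell proportions of a published frontal-crash cohort), 8% of
  crashes masked as rollovers, 5%/3% of belt/airbag fields masked unknown,
  PDOF uniform on a 9-to-1-o'clock frontal arc, and ejection essentially an
  unbelted phenomenon.
* **Sampling**: every occupant is assigned to one of 8 strata x 3 PSUs (24
  PSUs, the order of the real design), then Poisson-sampled with inclusion
  probability proportional to a logistic function of delta V
  (`sampling_severity_bias`, default 1; 0 gives an equal-probability
  design), mean `sampling_fraction` 0.08. Weights are Horvitz-Thompson
  inverses, so weighted totals estimate the population size unbiasedly.

All randomness flows from the single `seed`; sub-streams are derived by
fixed offsets, and the global RNG state of the caller is restored, so a
fixed seed makes every output byte-identical.

What the generator does **not** emulate: real PSU geography and its
intra-cluster correlation (PSU assignment here is random, so design effects
are mild), year-to-year weighting factors, the 800-variable schema, missing
delta V mechanisms that correlate with severity, and any dependence of
belt use on driver behaviour that would confound real data. Passing tests
therefore demonstrate that the estimator and decision logic are correct
under the declared mechanism — not that any particular real-world cohort is
confounder-free.

## Validation and problem sizes

The test suite validates each layer at sizes chosen to keep a full run in a
few minutes while leaving Monte-Carlo noise well below the margins tested:

* fitter vs an independent maximum-likelihood oracle (base `glm`) to 1e-6 on
  equal-weight data of up to 200 rows;
* truth recovery: 100 replicates at population 2e5 — the per-mph delta V
  and belt coefficients are recovered with under 5% bias and 95% CI
  coverage inside [90%, 98%];
* test size: under a null belt effect (200 replicates, population 3e4) the
  Wald difference test at a mid-range profile rejects at close to its
  nominal 5%;
* the case-study decision pattern: at a population of 8e4 — fifteen years
  of roughly 5,500 investigated crashes per year, the scale of the real
  sample — a 56 mph frontal case yields overlapping intervals, a
  non-significant difference, and a failed gate at every seed tried, while
  the textbook 30%/10% two-point cohort passes the gate with apportionment
  0.20.

The simulated-risk checks use binomial 3-sigma bands per delta V bin; the
Horvitz-Thompson check uses 200 replicate designs against a 2-standard-error
band.

## Known limitations

* Variance is linearization-only; replication methods (BRR, jackknife) are
  not provided.
* The injury outcome uses only the AIS severity digit of the 7-digit injury
  code; the leading six digits are preserved opaquely but not decoded, so
  body-region-specific outcomes (e.g. "serious head injury") require
  pre-filtering by the caller.
* No imputation: records with unknown belt, airbag, or delta V are excluded
  at the declared stages, which assumes unknownness is unrelated to risk
  given the model covariates.
* The gate logic evaluates one exposure (belt non-use) for one occupant;
  multi-defendant or multi-exposure apportionment is out of scope.
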