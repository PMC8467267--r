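# crashcausal

Evidence-based quantification of the effect of seat belt non-use in
crash-related civil litigation.

When a crash injury claim is met with a contributory-negligence defence —
"the claimant was unbelted" — the case-specific question is counterfactual:
*how much more likely was this injury or death because the occupant was not
wearing a seat belt, in this particular crash?* `crashcausal` answers it the
way a forensic epidemiologist would:

1. **Cohort construction.** Occupant-level records from a NASS-CDS-like
   stratified multistage crash sample are filtered to crashes comparable to
   the litigated one (occupant role, frontal PDOF window such as 9–11
   o'clock, no rollover, belt and airbag status known, year range), with a
   count-conserving exclusion ledger.
2. **Survey-weighted risk model.** A logistic model of the binary outcome
   (30-day death, or serious injury at an AIS cut point) over delta V, belt
   non-use, and covariates, fitted by pseudo-maximum likelihood with the
   national inflation weights; variance is the Taylor-linearized (sandwich)
   estimator with PSU-level clustering within strata.
3. **Decision calculus.** At the case profile, with `p1` the unbelted and
   `p0` the counterfactual belted risk:

   - relative risk `RR = p1/p0`,
   - attributable risk `AR = (RR − 1)/RR × 100% = (p1 − p0)/p1 × 100%`,
   - absolute risk difference `p1 − p0`.

   The "more probable than not" legal standard passes only when `AR > 50%`
   (equivalently `RR > 2.0`, strictly) **and** the difference is
   statistically supported. Only then is the claimant's contributory share
   quantified — as the **absolute** risk difference under the default
   contributory-negligence framing, or the attributable fraction under the
   product-defect framing.

Because national crash microdata cannot ship with a package, `crashcausal`
includes a fully parameterised synthetic generator (`generator_params()`,
`simulate_crash_sample()`) with a known logistic death mechanism,
right-skewed delta V distribution, and severity-biased Horvitz–Thompson
sampling, so every stage is testable against closed-form truth.

## Worked example

A 56 mph frontal crash (PDOF 10:30, airbag deployed, unbelted pickup
driver), analysed against a synthetic 80,000-occupant crash population:

```r
library(crashcausal)

cfg <- run_config(
  case = case_spec(delta_v_mph = 56, belt_used_actual = "not_used",
                   airbag_deployed = "deployed", body_type = "pickup",
                   model_year = 2005, pdof = "10:30"),
  generator = generator_params(n_population = 8e4),
  seed = 2021)
rep <- run_pipeline(cfg, output_dir = "case_out")
cat(rep$narrative)
```

```
At a delta V of 56.0 mph, the modelled risk of the outcome is 60.5% unbelted (95% CI 46.4-73.0%) and 70.7% belted (95% CI 64.8-76.0%).
Relative risk 0.9; attributable risk -17%; absolute risk difference -10.2 percentage points.
Wald difference test: z = -1.39, p = 0.165 (not significant at alpha = 0.05); 95% CIs overlap.
Belt non-use appears protective at this profile (RR < 1); this finding is surfaced, not clamped.
Gate FAILED: non-use not proven causal at the more-probable-than-not standard; apportionment 0.
Risk exceeds 50% for both belt states: the outcome was more probable than not regardless of seat belt use.
```

Read: at this extreme severity the belted and unbelted risk curves have
crossed and both exceed 50%; the apparent protection of non-use is not
statistically distinguishable from noise (high-speed crashes are sparse in
the data), so non-use is not proven causal and the contributory share is 0
— death was more probable than not regardless of belt use.

The calculator layer is usable on its own for published two-group risks:

```r
risk_ratio(0.30, 0.10)               # 3.0
attributable_risk(3.0)               # 66.7  (> 50: gate arithmetic passes)
absolute_risk_difference(0.30, 0.10) # 0.20  (the contributory share)
```

`run_pipeline()` writes `data.csv` (when simulated), `risk_curve.csv` (the
belted/unbelted death-risk curves over 30–80 mph with 95% bands),
`report.json`, and a plain-text narrative. The same config and seed
reproduce every output byte-for-byte. A thin CLI wraps the same functions:

```sh
exec/crashcausal run --config case.json --out results/
exec/crashcausal simulate --params gen.json --seed 7 --out data.csv
```

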