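---
title: "Methods: translating short-term wound-healing dynamics into cost consequences"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: translating short-term wound-healing dynamics into cost consequences}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(picost)
```

## The problem

Electrical stimulation (ES) is an adjunctive therapy for pressure injuries
(PIs) whose clinical effect is usually observed over short windows — here, a
14-day randomized double-blind 2×2 crossover in 12 patients with deep PIs.
Adoption decisions, however, hinge on longer-horizon, facility-level
quantities: how many healing days an intervention saves, what those days are
worth, and whether the saving clears the delivery costs. `picost` implements
that translation as an explicit, fully parameterized chain, so every
assumption is a named, testable input.

## Effect model

For each period, the daily wound-area reduction is
`(area_start − area_end) / 14` in cm²/day; wound growth gives negative
values and is never clipped. The primary effect is the within-subject
difference Δ (ES minus placebo), summarized by its mean, a Student-t
confidence interval on n − 1 degrees of freedom, and a paired t-test.
The Wilcoxon signed-rank check drops zero differences and mid-ranks ties;
for n ≤ 15 the p-value is computed from the exact 2ⁿ sign-assignment null
distribution (which remains valid under ties, where the tabulated
distribution does not), and from `stats::wilcox.test` beyond.

Crossover diagnostics follow the classical simple-crossover contrasts:
with `d = period1 − period2` per patient, the treatment effect is
`(mean d | ES-first − mean d | placebo-first)/2`, the period effect the
analogous sum contrast, and the sequence (carryover) effect the
between-sequence difference of within-patient sums, each with an
equal-variance two-sample t-test — the appropriate level of machinery for a
12-patient diagnostic, not a definitive inference. A first-period-only
contrast (parallel-groups view of period 1) is also reported.

The acceleration ratio `r = mean(red_ES)/mean(red_placebo)` is deliberately
secondary: ratios are unstable when the denominator straddles zero, so Δ
carries the causal claim and r only the economic translation. The headline
base case carries r as the configurable constant `base_case_ratio()` = 3.52;
the ratio of the two-decimal period means (0.179/0.051) is 3.51, the
difference arising from unrounded patient-level means. The "median-based"
ratio is ambiguous in general: we default to the ratio of period medians,
because the median of per-patient ratios explodes whenever one patient's
placebo reduction is near zero — the opposite of the robustness such a
summary is meant to provide. The per-patient variant remains available as
`ratio_summary(, "per_patient_median")`; neither is asserted to reproduce
any particular published value, which cannot be recovered without the
original patient-level data.

## Healing-time translation

Baseline time to heal under usual care is imputed by stratified medians: a
depth × DESIGN-R-category table (defaults: superficial 15/33/140 days, deep
26/63/259 days for ≤9 / 10–18 / ≥19 points). Boundaries are inclusive
integers, so 9 falls in ≤9 and 10 in 10–18; DESIGN-R totals are integers so
no ambiguity remains. The table is validated to be positive and
non-decreasing across severity within each depth.

Two translation rules map `T_placebo` to `T_ES`:

* **constant_ratio** — `T_ES = T_placebo / r`. Linear in `T_placebo`,
  strictly decreasing in r; multiplying the whole table by k multiplies
  baselines, days saved and gross offsets by exactly k.
* **diminishing** — the acceleration observed over the 14-day treatment
  window is not assumed to persist: progress accrues at relative rate r for
  the first `accel_window_days` (default 14, the window over which the
  effect was measured), then at `r_late = 1 + κ(r − 1)`. κ ∈ [0, 1] is the
  retained fraction of the acceleration (default 0.5, the midpoint between
  "no late benefit" κ = 0 and the base case κ = 1, which recovers
  constant_ratio exactly). Closed form: `T_placebo/r` if
  `T_placebo ≤ r·w`, else `w + (T_placebo − r·w)/r_late`. The test suite
  verifies this closed form against a brute-force day-stepping simulator
  (0.001-day increments) to within 0.01 days over a parameter grid.

Where a cohort (rather than a single stratum) is translated, the rule is
applied per patient and averaged. Under constant ratio the two orders are
identical; under the diminishing rule they differ, and the per-patient order
was chosen because the attenuation is a per-wound, not per-cohort,
assumption.

## Cost model

The per-day healing-related monetary value is a provider-perspective proxy,
default JPY 4000/day = procedures 1000 + labor 1500 (30 min × JPY 50/min) +
support surface 500 + nutrition 1000. It is a budget-impact proxy, not a
societal cost; the scenario grid varies it over 3000–10,000 JPY/day.

ES implementation costs split into a fixed per-case part — device allocation
`round(77,000 / 12)` = 6,417 (rounded to whole JPY before summing, keeping
the printed arithmetic chain 6,417 + 3,600 = 10,017 intact) plus single-use
consumables 3,600 — and a variable part, incremental ES staff time (15
min/day × JPY 50/min = 750 JPY/day) accruing over **every** day of `T_ES`.
The average implementation cost per treatment day amortizes the fixed part:
`C_impl/day = fixed/T_ES + 750`. Net impact is `gross − (fixed + 750·T_ES)`,
algebraically identical to `gross − C_impl/day × T_ES`; the suite asserts
the identity on randomized inputs. The break-even threshold
`v·(T_placebo − T_ES)/T_ES` (= `v(r − 1)` under constant ratio) is the
average per-day implementation cost at which net impact crosses zero, and
`net > 0 ⟺ C_impl/day < break-even` holds by construction. Monetary
outputs are kept at full precision internally and rounded half-away-from-zero
to whole JPY only at reporting (`round_jpy()`). Negative days saved (r < 1)
flow through to negative offsets rather than being floored, so downside
scenarios remain visible.

Stratum-level projections fix `T_placebo` at each stratum's published median
(not the within-stratum mean of patient baselines, which is the same number
by construction) and report patient counts alongside.

## Bootstrap uncertainty

Uncertainty is propagated by a patient-level nonparametric bootstrap:
resample n patients with replacement, recompute r as a ratio of resample
means, re-impute the mean baseline from the resample's stratum mix (so
cohort-composition uncertainty propagates; `t_placebo_fixed` switches this
off for stratum tables), and push everything through the cost chain. 95%
uncertainty intervals are 2.5th/97.5th percentiles with linear interpolation
between order statistics (`quantile(type = 7)`), stated explicitly so
results are reproducible across languages. Default 10,000 iterations,
seeded and bit-reproducible.

Resamples with non-positive placebo mean leave r — and hence `T_ES` —
undefined. They are excluded from percentile computation, counted in
`n_degenerate`, and warned about when they exceed 1% of iterations. Extreme
but positive r draws are deliberately retained: they are genuine sampling
instability of a small-denominator ratio, and their influence is examined
instead through the trimmed-ratio summary (mean of draws strictly inside the
2.5–97.5 percentile band, requiring ≥ 40 retained draws) and the
median-based scenario.

The engine is verified two ways: on 3-patient cohorts its draw distribution
is compared with the exhaustive 27-atom resample distribution (CDF agreement
within Monte-Carlo error at 100,000 iterations), and an interval-calibration
study checks the 95% interval's coverage of a known population ratio over
1,000 replications of 12-patient cohorts with 10,000 resamples each.
A limitation surfaced by that study is worth stating plainly: percentile
bootstrap intervals at n = 12 sit near the lower edge of nominal coverage
(the well-known small-sample deficiency of percentile intervals — they
behave like z- rather than t-intervals), so the 95% UIs reported by this
package at trial scale should be read as approximate.

## Synthetic cohort generator

No patient-level data are published, so the generator emulates the study
conditions: 12 deep-PI patients, 5 in DESIGN-R 10–18 and 7 in ≥19, 14-day
periods, and cohort mean daily reductions of exactly 0.179 (ES) and 0.051
(placebo) cm²/day. Per-patient reductions are drawn from a bivariate normal
and affinely recentred onto the targets, so Δ = 0.128 and the mean-based r
are reproduced by construction for every seed. Dispersion defaults —
sd 0.15 (ES), 0.08 (placebo), correlation 0.5 — were fixed once so that the
implied sd of within-patient differences (≈ 0.13 cm²/day) matches the width
of the published Δ confidence interval at n = 12; they are parameters, not
estimates. Start areas are lognormal (log-mean ln 8 cm², log-sd 0.5:
strictly positive, right-skewed, typical PI scale); an end area that would
fall below zero is floored at 0 cm² by raising that period's start area to
`14 × reduction`, which preserves the patient's reduction (and therefore the
exact calibration) while logging the event in `n_floored`. Sequences are
assigned alternately then shuffled by the seed; DESIGN-R totals are uniform
integers within each category (19–28 for ≥19). Placebo reductions may be
negative — wounds do grow — which is exactly what makes the ratio unstable
and the bootstrap's degenerate-draw policy necessary.

`calibrate = FALSE` disables the recentring for population-sampling
simulation studies (e.g. the coverage experiment above), where the targets
act as population means and cohort means must vary.

What the generator does **not** emulate: measurement error in wound tracing,
within-period nonlinearity (only endpoint areas enter the model), informative
dropout, or any dependence of healing rate on severity stratum. Passing
tests therefore demonstrate the arithmetic and statistical machinery on data
matching the published summary statistics — not that the published data
themselves are reproduced.

## Scenario suite

Scenarios are declarative (`scenario_spec()`), so the prespecified analyses
are data, not code: the per-day value grid (3000–10,000), ratio ±20%,
baseline ±20% and ±30%, the alternative ratio summaries, and the
diminishing-acceleration variant — bundled as `standard_scenarios()`.
Scenario runs are pure functions of their inputs. The depth-unstratified
structural variant requires an explicit alternative table: the medians such
an analysis should use are not derivable from the stratified ones, and
inventing a pooled default would fabricate data. A clearly marked synthetic
example (deep-row medians applied to all depths) ships in
`inst/extdata/unstratified_table_synthetic.csv`. Configuration files
(YAML/JSON, see `inst/extdata/example_config.yaml`) can express every
parameter block; `read_config()` reconstructs the objects with package
defaults for omitted fields.

## Numerical and testing choices

Problem sizes in the test suite were chosen to keep the full run around half
a minute while leaving Monte-Carlo error well inside the asserted
tolerances: 400-seed parameter-recovery loops for the crossover contrasts,
100,000-iteration bootstrap versus the exhaustive n = 3 distribution, and
the 1,000 × 10,000 coverage study. Exhaustive enumeration backs the
small-n Wilcoxon and bootstrap checks; a day-stepping simulator backs the
diminishing-mode closed form; a root-finding solve backs the break-even
closed form. CSV round-trips write doubles at 17 significant digits so
re-reading is exact.

## Known limitations

* The constant-ratio extrapolation from a 14-day window to a multi-month
  healing trajectory is a strong structural assumption; the diminishing mode
  bounds it from the conservative side but is itself a two-phase
  simplification.
* Baseline times to heal are external medians used as structural inputs, not
  observed outcomes; the ±20/30% sweeps show how directly they scale every
  downstream quantity.
* Percentile bootstrap intervals at n = 12 are approximate (see above);
  BCa or studentized intervals are out of scope.
* All monetary outputs are facility-level proxies in nominal JPY; no
  discounting, inflation adjustment, or comparison against alternative
  therapies is modelled.
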