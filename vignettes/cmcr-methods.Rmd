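---
title: "Methods: complexity categorization, the adherence indicator, and AR(1) trend analysis"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: complexity categorization, the adherence indicator, and AR(1) trend analysis}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(cmcr)
```

## 1. The categorization model

A categorization matrix scores *n* clinical variables on three severity
levels — X (1 point), Y (2 points), Z (3 points) — so a complete assessment
has total score TS in [Σx, Σz] with Σx = n, Σy = 2n, Σz = 3n. Low
complexity is the single score TS = Σx (every variable at its mildest
level); medium is Σx+1 … Σy; high is Σy+1 … Σz. These three ranges tile
[Σx, Σz] exactly, which the test suite verifies for n = 1…20.

The model's central assumptions are that (i) each variable contributes
equally (one to three points, no weights), (ii) severity is ordinal within
each variable, and (iii) the category, not the raw assessments, drives the
therapeutic response (sessions per time unit). The package deliberately
keeps the per-variable level breakdown in every `cmcr_result`: two patients
with the same category can have different clinical drivers and be managed
under different protocols, and discarding the breakdown would make the
result unauditable.

### Interval conventions and the gap policy

Printed thresholds are taken literally, including open/closed bounds:
handgrip "> 30 kg" is strictly greater, "27–30 kg" is the closed interval.
Several cells of the pulmonary matrix leave genuine holes between printed
intervals (PEEP between 6 and 7 or between 9 and 10; FiO2 in (30, 31) or
(50, 51); static compliance in [34, 35) or (49, 50]). A value landing in a
hole is resolved by the variable's `gap_policy`:

* `nearest-worse` (default): assign the more severe of the two levels whose
  printed intervals are adjacent to the value. This is clinically
  conservative — when the rubric is ambiguous, the patient is treated as
  sicker, never healthier.
* `error`: refuse, for sites that prefer to widen their intervals
  explicitly.

The policy is per-variable and survives serialization, so an institution
can override it without touching code. Minute volume has no hole under the
literal reading ("< 7" then "7–12": the value 7 belongs to the closed
2-point interval), so the gap policy never fires there.

### Not-measurable values

The printed tables place "not measurable" asymmetrically: for the motor
variables (MRC-Sum Score, FSS-ICU) it appears in the 3-point column — an
unassessable patient is assumed severely impaired — while for static
compliance it shares the 1-point column with "> 50 cmH2O", because
compliance cannot be measured once the patient no longer receives
controlled ventilation, which is a *good* sign. The package preserves this
asymmetry exactly (`not_measurable_level` per variable) rather than
"fixing" it.

### The compound PEEP/FiO2 criterion

The ventilatory cell prints paired thresholds with no combination rule.
Each component is leveled independently and the worse level is kept —
consistent with the conservative gap policy. A different rule (e.g.
averaging) would be a modeling invention with no support in the rubric.

### S5Q boundary

The cooperation score prints "4–5", "3", "< 2", leaving the value 2
uncovered if "< 2" is read strictly. It is read as ≤ 2 so the 0–5 scale has
no hole; reading it strictly and relying on the gap policy would give the
same assignment (the more severe neighbour of 2 is the 3-point level), so
the choice is visible only in the config, not in behavior.

### Missing variables and the time budget

An assessment missing a variable is a hard error by default: partial
assessments have no defined semantics in the model. An opt-in
`on_missing = "worst"` mode imputes level Z, mirroring how the tables treat
unmeasurable values; imputed rows are flagged in the audit trail. The
recommended 15–30 minute completion window is metadata, not enforced
behavior. Therapeutic loads are not printed anywhere in the source model,
so the package refuses to invent defaults and requires an explicit,
monotone non-decreasing `load_map`.

## 2. Re-categorization schedules

Three policies cover the described practice: `daily` (due when the calendar
day advances), `weekly-on-fixed-weekday` (due on the configured weekday if
none was recorded that day — Wednesday in the originating service), and
`on-event` (due when a watched event, e.g. a ventilatory-support change
after extubation, occurred since the last categorization). When an event
triggers a same-day re-categorization, both records are kept; the adherence
indicator counts care instances, not categorizations, so duplicates cannot
inflate it.

## 3. The adherence indicator

Adherence in quarter *q* is 100 × (categorized instances) / (eligible
instances). Two denominator policies are first-class because the source
material uses both framings: `all-instances` (every recorded instance of
inpatient care) and `prescribed-only` (only instances with a
physical-therapy prescription; under this policy a categorized,
non-prescribed instance is a validation error). Neither is "the" correct
one; the choice is logged with every CLI run.

Quarters are contiguous calendar quarters anchored at the window's first
quarter (2011-Q3 for the study period, so t = 1 ↔ Jul–Sep 2011). Note that
July 2011 through December 2015 inclusive spans 18 calendar quarters; a
17-quarter series over that period therefore cannot touch both endpoints,
and the package never forces one to. Zero-denominator quarters are emitted
with a missing adherence value rather than dropped, so a gap is visible to
the analyst instead of silently shortening the series. Aggregation is a
pure function of the instance multiset — idempotent and invariant under row
order, verified by property tests.

## 4. Trend estimation

### Prais-Winsten regression

`prais_winsten_fit()` estimates y_t = β₀ + β₁ t + ε_t with
ε_t = ρ ε_{t−1} + u_t by iterated feasible GLS:

1. ordinary least squares of y on (1, t);
2. ρ̂ = Σ e_t e_{t−1} / Σ e_{t−1}² over the current residuals;
3. Prais-Winsten transform: the first observation is retained, scaled by
   √(1 − ρ̂²); subsequent rows are quasi-differenced (y_t − ρ̂ y_{t−1},
   same for both regressor columns);
4. refit on the transformed data; iterate until |Δρ̂| < 1e−6 (cap 100).

Retaining the first observation distinguishes Prais-Winsten from
Cochrane-Orcutt and matters at n = 17, where dropping a point costs real
information. At a fixed ρ̂ the transformed OLS equals exact GLS under the
stationary AR(1) covariance, which the suite checks against a closed-form
(X'Σ⁻¹X)⁻¹X'Σ⁻¹y oracle. If an iteration leaves the stationary region, ρ̂
is clamped to ±0.999, a warning is raised and `converged` is set to
`FALSE`. A (near-)perfectly linear series short-circuits to ρ̂ = 0 rather
than dividing ~0 by ~0.

Inference uses the t distribution with n − 2 degrees of freedom on the
transformed fit, the common single-step convention, with no small-sample
correction for the estimation of ρ. A consequence worth knowing: in
17-point series the feasible-GLS standard errors are optimistic, because ρ̂
is estimated from few residuals and is biased toward zero; the package's
own Monte-Carlo acceptance test measures the empirical coverage of the
nominal 95% slope interval under these conditions and finds it below
nominal (high-80s percent). Point estimation is unaffected — the same test
shows the mean slope bias is negligible — but p-values near the threshold
should be read with this in mind, and exact replication of p-values
produced by other software (which may use two-step estimation or different
semidifferencing variants) is not promised.

### Comparing two groups

The between-group comparison is implemented as the joint model
y = β₀ + β_g·g + β_t·t + β_gt·(g × t) with a single AR(1) error
coefficient, estimated by the same transform applied within each group's
run (each group's first observation gets the √(1 − ρ²) scaling); degrees of
freedom are N − 4. The interaction coefficient β_gt *is* the slope
difference (group A − group B), and its t test is the trend comparison.
This is the repeated-measures-with-AR(1)-errors structure that tests
exactly the quantities of interest — slope difference and level difference
— on short quarterly series. Because the level contrast depends on where
along the series it is evaluated, the package reports both the raw mean
difference ȳ_A − ȳ_B and the model contrast at the mean quarter
(β_g + β_gt·t̄); for series on a common grid the two coincide up to
estimation noise.

## 5. The synthetic-record generator

The generator's defaults are the study conditions the analyses assume:
Q = 17 quarters from 2011-Q3; ICU adherence starting at 63% and gaining
1.28 pp/quarter; non-ICU starting at 54% and gaining 1.62 pp/quarter; AR(1)
disturbances with ρ = 0.3 (the autocorrelation magnitude reported for the
indicator) and Gaussian innovations with sd = 2 pp — the noise law is a
package choice, as the source material implies nothing about it. The
disturbance is initialized at its stationary distribution
(ε₁ ~ N(0, sd²/(1 − ρ²))), so every quarter has the same marginal variance.
Targets are clipped to [0, 100]. Default volume is 430 instances per group
per quarter: the study's ~8,600 instances/quarter scaled down tenfold and
split between units, keeping tests fast while preserving proportions.

Care instances realize the target as independent Bernoulli(y_t/100) draws
among prescribed instances, with dates uniform within the quarter. Two
consequences are worth stating. First, binomial sampling noise adds white
noise on top of the AR(1) disturbance, so the lag-1 autocorrelation
*observable* in a finite-volume adherence series is diluted below the
configured ρ — and at n = 17 the ρ̂ estimator is additionally biased toward
zero. The suite therefore checks ρ recovery on long series, where the
estimator is consistent, and treats short-series ρ̂ as descriptive.
Second, instances are independent across quarters; the generator does not
model patient trajectories, accreditation-driven adherence peaks, or any
case-mix drift. Passing tests on this generator show the pipeline's
arithmetic and inference are correct under the stated process — not that
real hospital data follow that process.

Assessment generation inverts the scoring: for a target category it samples
uniformly among the level combinations whose total score lands in the
category's range (3ⁿ combinations are enumerated exactly), then samples a
raw value inside each chosen criterion cell — interval endpoints with
configurable probability (default 0.1, to exercise boundaries), the
not-measurable marker with probability 0.1 where the matrix allows it, and
at least one component of a compound cell realizing the target level.
Values are rounded to one decimal after shrinking open bounds by 0.1, so
rounding can never push a value across a criterion boundary.

## 6. Problem sizes and numerical choices in the test suite

The suite enumerates all 3⁴ = 81 and 3⁶ = 729 level combinations of the
built-in matrices against a brute-force range oracle; sweeps every numeric
domain in 0.25-unit steps for exhaustiveness; uses 1000 simulated 17-point
series for slope bias and interval coverage; 200 seeded end-to-end pipeline
replicates at 200 instances/group/quarter for parameter recovery (recovered
slopes within ±0.15 pp of the configured 1.28 and 1.62); and a
145,968-instance fixture reproducing the published pooled categorization
ratio (96,400/145,968 = 66.04%). Convergence tolerance for ρ̂ is 1e−6;
comparisons against closed-form oracles use 1e−8…1e−12.

## 7. Known limitations

* The scoring engine supports three rule kinds (numeric interval, label
  set, not-measurable); richer rules (e.g. cross-variable logic) are out of
  scope by design.
* The adherence indicator is instance-based with no patient-level
  follow-up and no case-mix adjustment; it measures recording behavior,
  not patient outcome.
* Feasible-GLS inference is optimistic in very short series (above);
  bootstrap or bias-corrected alternatives are deliberately not bundled.
* The XLSX reader assumes a sheet laid out like the CSV schema; arbitrary
  spreadsheet layouts need the `col_map` argument or prior export to CSV.
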