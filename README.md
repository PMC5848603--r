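# cmcr — complexity-based model for categorizing rehabilitation

`cmcr` is an R implementation of a complexity-based categorization model for
rehabilitation in acute hospitals, together with the quality-indicator
machinery used to monitor whether clinicians actually use it. It is aimed at
rehabilitation services, physical-therapy departments and clinical
informatics teams who want to (a) run severity-scored categorization
matrices over standardized assessments, (b) track adherence to the model as
a quarterly indicator, and (c) analyse adherence trends with autocorrelated
time-series regression.

## The model

A categorization matrix lists *n* clinical variables (rows), each assessed
on three severity levels (columns): **X** (mildest, 1 point), **Y**
(2 points) and **Z** (most severe, 3 points). For one patient assessment the
per-variable points are summed into the total score

> TS ∈ [Σx, Σz],  with Σx = n, Σy = 2n, Σz = 3n,

and TS is bracketed into a complexity category:

| Category | Score range |
|---|---|
| Low complexity | TS = Σx |
| Medium complexity | Σx + 1 ≤ TS ≤ Σy |
| High complexity | Σy + 1 ≤ TS ≤ Σz |

Each category is associated with a therapeutic load (sessions per time
unit; values are institution-specific and must be supplied as config). Two
matrices ship with the package, reproduced cell-for-cell from the published
model:

- `icu_motor` — motor rehabilitation for ICU patients (MRC-Sum Score,
  FSS-ICU, handgrip dynamometry with sex-specific thresholds, S5Q; n = 4,
  categories 4 / 5–8 / 9–12);
- `pulmonary_imv` — adult pulmonary rehabilitation under invasive
  mechanical ventilation (auscultation, ventilatory assistance, secretion
  amount, minute volume, compound PEEP/FiO2, static compliance; n = 6,
  categories 6 / 7–12 / 13–18).

Custom matrices are plain YAML/JSON documents (see
`inst/extdata/matrices/`): numeric intervals with explicit open/closed
bounds, label sets, optional sex-conditional intervals, an optional
not-measurable level, and a per-variable `gap_policy` that resolves values
falling between printed intervals (default `nearest-worse`: the more severe
adjacent level).

**Adherence indicator.** From a log of inpatient-care instances (one row
per instance, with a physical-therapy-prescribed flag and a categorized
flag), `aggregate_quarters()` builds the quarterly adherence series:
100 × categorized / eligible instances, per quarter, overall and by unit
(ICU / non-ICU), under either denominator policy (`all-instances` or
`prescribed-only`).

**Trend analysis.** `prais_winsten_fit()` estimates the linear trend
y_t = β₀ + β₁ t + ε_t with AR(1) errors ε_t = ρ ε_{t−1} + u_t by iterated
feasible GLS (Prais-Winsten: the first observation is kept, scaled by
√(1 − ρ²)). `compare_trends()` stacks two series into a group × time
interaction model with a common AR(1) coefficient and reports the slope
difference, its p-value, and the group level difference.

**Synthetic records.** `sim_config()` / `simulate_epr()` /
`simulate_assessments()` generate seeded synthetic care logs and assessment
tables with the statistical structure above, so the entire pipeline is
testable without any patient data.

## Worked example

```r
library(cmcr)
m <- cmcr_matrix("icu_motor")
categorize(list(patient_id = "P0042",
                values = list(mrc_sum = 45, fss_icu = 30, handgrip = 33, s5q = 5),
                sex = "male"), m)
```

```
TS = 5 -> medium complexity  [matrix icu_motor; patient P0042]
 variable level points imputed
  mrc_sum     Y      2   FALSE
  fss_icu     X      1   FALSE
 handgrip     X      1   FALSE
      s5q     X      1   FALSE
```

An MRC sum of 45 falls in the 2-point band (37–47) while the other three
assessments are in their mildest band, so TS = 2+1+1+1 = 5, just above the
low-complexity score of 4. The full pipeline on synthetic data:

```r
cfg <- sim_config(seed = 2026)      # 17 quarters; ICU 63% +1.28 pp/q,
sim <- simulate_epr(cfg)            # non-ICU 54% +1.62 pp/q; AR(1) rho 0.3
agg <- aggregate_quarters(sim$instances)
compare_trends(adherence_series(agg, "ICU"),
               adherence_series(agg, "non-ICU"), groups = c("ICU", "non-ICU"))
```

```
Trend comparison: ICU vs non-ICU  (17 quarters per group)
  slope ICU: 1.2796 pp/quarter (p = 1.64e-05)
  slope non-ICU: 1.5428 pp/quarter (p = 1.77e-11)
  slope difference (joint model): -0.2346 pp/quarter, interaction p = 0.287
  mean level difference: 5.2120 pp (model contrast at mean quarter: 5.3006 pp)
  common rho = 0.1442
```

The estimated slopes recover the configured trends (1.28 and 1.62
pp/quarter) up to sampling noise; the ICU series sits about 5 pp above the
non-ICU series on average for this seed.

A command-line wrapper with the same pipeline ships at `inst/cli/cmcr`
(subcommands `categorize`, `adherence`, `trend`, `simulate`).

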