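---
title: "Methods: occupational CWP cohort analysis and risk stratification"
author: "cwpcohort"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: occupational CWP cohort analysis and risk stratification}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(cwpcohort)
```

This vignette documents the models, conventions and design choices
behind the package. The pipeline mirrors how a colliery occupational
health service analyses a dust-exposed workforce: reconstruct each
worker's exposure from the job-spell record, estimate cumulative
incidence of coal workers' pneumoconiosis (CWP) by subgroup, project the
future case burden, and stratify the unaffected workforce into
surveillance classes.

## Cohort model and exposure reconstruction

A worker record couples demographics (birth year, first-exposure date),
an ordered list of non-overlapping job spells (work area, half-open
`[start, end)` date interval), an outcome flag, and a diagnosis or
censor date. Durations are days/365.25. Records with under one year of
total exposure are rejected — the conventional inclusion rule for these
cohorts.

**Occupational classification.** The cascade, applied to per-area
duration sums: a single consistent area keeps its label; tunneling more
than half of total exposure → tunneling; otherwise tunneling under 2
years with mining more than half → mining; otherwise tunneling at least
2 years (but not more than half) → combining; all else → helping. Two
boundary conventions the prose rules leave open are fixed here:
*exactly half is not "more than half"*, and *exactly 2 years of
tunneling is combining-eligible*. The inclusive 2-year boundary avoids a
dead zone in which no rule before the fallback could fire. Segment
order never matters (property-tested).

**Cumulative dust exposure.** CDE (mg/m³·years; reports print the
field's customary "mg-years") is the sum over spells and overlapped
calendar years of (days of overlap)/365.25 × the area-year geometric
mean concentration. The shipped concentration table resolves calendar
years at decade-block resolution (1970-, 1980-, 1990-, 2000-), the
resolution at which such monitoring summaries are published; a per-year
table can override it. CDE is exactly additive under splitting any
spell at any date (tested at 1e-9 relative), and equals a per-day
brute-force sum by construction.

**Observation window.** Follow-up runs from first exposure to diagnosis
(cases — this equals the latency) or to the censor date (study end
2011-12-31, or loss to follow-up). Overlapping spells are rejected
rather than merged, because published durations in these cohorts are
sums of disjoint spells; employment gaps simply accrue no duration.

## Synthetic cohort generator

No individual-level data of this kind are public, so the generator is a
first-class module with ground truth. Defaults describe the study
conditions and are not tuning knobs:

| parameter | default | meaning |
|---|---|---|
| `n_workers` | 17,023 | cohort size |
| `category_mix` | 7.0/15.8/12.5/64.7% | tunneling/mining/combining/helping |
| `era_mix` | 36.2/35.8/28.0% | entry decades 1970-/1980-/1990- |
| age at entry | 21.4 ± 4.0 y, in [16, 40] | truncated normal |
| latency | 29.1 ± 5.3 y, ≥ 5 y | onset delay for converters |
| career duration | 23.0 ± 10.4 y, in [1, follow-up] | exposure years |
| subgroup rates | 8.1/8.0/6.5/0.6‰ (1970-); 1.7/2.1/1.4/0.3‰ (later) | annual incidence |

Entry dates are uniform within the era (1990- extends to the 2010
inclusion cut-off); spell histories are constructed so the
classification cascade provably returns the assigned category, with
margins so whole-day rounding cannot flip a boundary rule.

**Onset models.** Three regimes are provided because downstream stages
need different fidelities:

* `"linear"` (default) — conversion by exposed year *t* with probability
  *r·t* (per-year conditional hazard *r*/(1 − *r·k*)). This is exactly
  the constant *annual-average-incidence* model that the life-table
  summary CI(T)/T assumes, so the estimator recovers the configured
  rate in expectation. A geometric/exponential per-year hazard would
  instead give CI(40) = 1 − (1 − r)⁴⁰, which at 8.1‰ falls ~14% below
  r×40 — irreconcilable with rate recovery at realistic rates; we
  therefore reserve true constant hazard for its own regime.
* `"exponential"` — a genuine constant-hazard event-time process, used
  to validate the life-table estimator against the closed form
  1 − e^(−λt).
* `"cde"` — conversion probability logistic in log10(CDE), giving the
  risk model a learnable dose–response signal.

Under the default regime the onset *decision* runs over exposed years
while the diagnosis *date* is entry + latency; a converter whose
latency exceeds the administrative window is censored as a non-case.
Deaths before study end are not simulated — life expectancy enters only
the projection stage. Era and category are sampled independently (the
real joint distribution is unpublished), so the generator reproduces
marginals, not any era×category×age interaction. Consequently, passing
tests demonstrate estimator correctness under these stated conditions,
not agreement with any particular workforce: on the default cohort the
estimated subgroup rates sit below the configured values simply because
careers (mean 23 y) are shorter than follow-up horizons (up to 42 y) —
as in real cohorts, where the "annual average" dilutes exposure-driven
risk over the whole observation span.

## Life tables and curve comparison

Actuarial construction on 1-year intervals since first exposure
(configurable width): events and withdrawals fall in the interval
containing their time, the effective denominator half-weights
withdrawals (n′ₖ = nₖ − wₖ/2), and CI(t) = 1 − Π(1 − qₖ). The actuarial
correction is the canonical reading of "life-table method" in
occupational epidemiology; with no withdrawals before *t* the estimate
reduces exactly to the empirical event fraction (tested). Ties between
an event and a withdrawal in one interval need no extra rule under this
estimator; events are tabulated first by convention.

The Peto log-rank weights each event time by the pooled product-limit
survival estimate computed through that time (no +1 small-sample
correction — the plainest reading of the method; `weights = "unit"`
gives the classic log-rank, which matches `survival::survdiff(rho = 0)`
to 1e-9 and is the cross-check used in tests). Multi-group comparisons
are run pairwise at df = 1 with no multiplicity adjustment, mirroring
the reporting style of such studies. Pearson χ² for baseline tables is
computed without continuity correction.

## Projection

Each worker without CWP contributes rate × m expected future cases,
m = max(0, LE − current age), *linearly and without compounding*;
published projections of this kind show identical totals in the first
two future decades, which only a non-compounding allocation produces
(`compounding = TRUE` provides 1 − (1 − r)^m as an alternative).
Remaining years are allocated to future windows (<10, 10–19, 20–29,
30–) by exact overlap, so the age-band and window tables are two
partitions of the same expectation and must agree to 1e-9 (enforced at
run time and equal to a per-worker per-year brute-force oracle in
tests). Life expectancy defaults to a scalar 74 y — a realistic figure
for male residents of a northern Chinese industrial region, the actual
value being unpublished — and can be an age-indexed table. 1990-
entrants use the 1980- rates (too few cases accrue in the youngest era
to estimate one), via a configurable mapping.

## Risk perceptron and stratification

Features: category (4-level) and era (3-level) as treatment dummies,
duration and CDE standardized (CDE optionally log1p first) — 7 encoded
inputs. The model is a single-hidden-layer perceptron with a logistic
output trained on cross-entropy via `nnet` (BFGS, small weight decay
1e-3, 400 iterations); hidden units default to 9 (82 weighted
connections with 7 inputs — the order of magnitude that "74 synapses"
reports of such models most plausibly describe) and are exposed as a
knob. The hidden
activation is `nnet`'s logistic sigmoid — the reference description of
such models does not fix an activation, and we prefer the stock,
deterministic implementation over a hand-rolled tanh network. Training
is seed-reproducible (the seed fixes the random initial weights). Class
imbalance is left unweighted by default, matching the
specificity ≫ sensitivity behaviour typical of this design; class
weighting is deliberately out of the default path.

**Importance** is permutation-based (loss increase when one input's
encoded columns are jointly permuted, floored at 0, normalized to sum
to 1); whether the original analysis tool used permutation- or
derivative-based importance is unknowable, so the label says what this
one is. **Calibration**: the high cutoff is the grid value whose
at-or-above count best matches round(projected_total × 1.5) — the
"protect 50% more workers than the projected cases" rule; the low
cutoff targets a designated low-risk pool (by default the post-1980
helping entrants, the subgroup with clearly declined incidence).
**Boundary convention**: text conventions "over 0.2"/"under 0.1"
conflict with interval labels "0.1-"/"0.2-" at the boundaries; the
package uses p ≥ cutoff → upper class, uniformly.

## Numerical and testing choices

* Dates are calendar `Date`s; intervals half-open; durations
  days/365.25 throughout, making CDE and duration sums exactly additive.
* CDE additivity and projection-oracle equality are asserted at 1e-9
  relative; probabilistic recoveries at 3 standard errors.
* Test problem sizes: life-table closed-form check at n = 10,000 over
  40 y; subgroup-rate recovery at n = 5,000 per subgroup with entry
  pinned so follow-up is 40 y and careers span it (the recovery
  property is about the estimator, so exposure must cover the horizon);
  Peto power check at 2,000 per arm, tenfold hazard ratio; perceptron
  checks at 1,200–4,000 records. These sizes give comfortable
  power/precision for every 3-SE band while keeping the suite quick.
* p-values are displayed to 3 decimals with a "<0.001" floor.

## Known limitations

* Decade-block concentrations smooth within-decade trends; CDE is
  semi-quantitative by construction.
* The generator emulates marginal structure and stated distributions
  only: no competing mortality, no job-transfer feedback, no
  radiographic profusion, no era×category dependence.
* Projections are point estimates; no uncertainty intervals (the
  underlying rates enter as constants).
* Cohort-level published results (e.g. 40-year cumulative incidences by
  category, or a specific model accuracy) depend on the unpublished
  personnel data and are not reproduction targets; what the tests
  guarantee is internal correctness against oracles and recovery of
  known synthetic truth.
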