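---
title: "Near-miss surveillance analytics: models, parameters, and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Near-miss surveillance analytics: models, parameters, and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(nearmiss)
```

## The problem this package models

A near miss is a safety event intercepted before it reached the patient.
Hospitals that count near misses face a chronic interpretive dilemma: a rise in
reports can mean deteriorating safety, improving reporting culture, or nothing
at all (more patients, more exposure). This package structures the analysis as
a three-level maturity pathway:

1. **Level 1** — hospital-wide standardized rates and a near-miss-to-harm
   ratio, monitored on attribute control charts;
2. **Level 2** — the same machinery stratified by unit/domain with
   domain-aligned denominators;
3. **Level 3** — severity weighting into a Near Miss Index, organizational
   learning yields at 90 and 180 days, and a deterministic interpretation
   matrix for leadership review.

Everything below documents the models, the tunable parameters, and the places
where a genuine design choice had to be made.

## Data model and validation

Events carry a three-way type (`near_miss`, `no_harm_incident`,
`harmful_incident`), a reached-patient flag, a detection mode, a unit/domain,
and an optional four-point severity class. Two coding rules are enforced as
hard invariants because the downstream formulas depend on them: a near miss
did **not** reach the patient, and a no-harm incident **did**. Violations are
quarantined (or abort the read in strict mode); validation is total, so every
input row is either accepted or appears exactly once in the validation report.

One deliberate asymmetry: unknown `unit_domain` codes are coerced to `"other"`
with a warning instead of being rejected. Level-1 analysis is hospital-wide,
and losing events to stratification vocabulary would bias the one level that
every adopter runs. Unknown codes in any *formula-bearing* field (type,
reached flag, severity) quarantine the row instead.

No-harm incidents are carried through I/O and counted in total reporting
volume (the `event_type = "all"` series used by the interpretation matrix) but
enter no rate formula: the near-miss rate numerator is near misses only and
the ratio denominator is harmful incidents only.

## Rates and denominators

The standardized rate is `count / exposure × scaling constant`, with the
scaling constant a convention of the denominator type: per 10,000 doses in
pharmacy, per 1000 patient-days, specimens, transfusion units, or procedures
elsewhere. Events are assigned to periods by the calendar month (or quarter)
of their event date; events are never fractionally apportioned.

**Stability threshold for quarterly aggregation.** Attribute charts misbehave
when per-period denominators are small, so monthly series are re-binned to
calendar quarters when any monthly denominator falls below a threshold. The
threshold ships as **500 exposure units per month** and is configurable. This
is an operational tunable, not an estimate: a numerator-based rule
("expected count ≥ 5") would be preferable in theory but requires the rate it
is meant to protect, so a denominator floor in the range where low-volume
domains (transfusion, small pharmacies) actually live was fixed once.
Aggregation is all-or-nothing per series so that a chart never mixes monthly
and quarterly points, and it conserves numerator and denominator totals
exactly — the quarterly rate is the exposure-weighted combination of its
months.

## Control charts

The u-chart is the standard attribute chart for rates with variable
denominators: center line \(\bar u = \sum c_i / \sum n_i\), per-period limits

\[ \bar u \pm 3 \sqrt{\bar u / n_i}, \]

with the lower limit floored at zero. Health-care count data are very often
overdispersed — between-month variation beyond Poisson — and a plain u-chart
then floods the dashboard with false special-cause signals. The Laney U′
chart rescales the limit half-widths by \(\sigma_z\), where
\(z_i = (u_i - \bar u)/\sqrt{\bar u / n_i}\) and \(\sigma_z\) is the mean
absolute moving range of consecutive \(z_i\) divided by 1.128 (the unbiasing
constant for moving ranges of span 2). Under pure Poisson variation
\(\sigma_z \approx 1\) and the two charts coincide.

Design choices worth knowing:

* **Selection threshold.** `select_chart()` uses the Laney chart when
  \(\sigma_z >\) 1.3 (configurable, always logged). There is no single
  published cutoff for "overdispersed"; 1.3 sits above the sampling noise of
  \(\sigma_z\) on typical 24–60-point series while catching dispersion strong
  enough to matter. The decision and the measured \(\sigma_z\) are recorded in
  the run log so a reviewer can second-guess it.
* **Underdispersion.** When \(\sigma_z < 1\) the selector still returns the
  plain u-chart. Shrinking limits manufactures signals; Laney shrinkage must
  be opted into by calling `build_laney_chart()` directly.
* **No limit freezing.** Limits are recomputed per period from each period's
  own denominator; there is no baseline window unless the caller fits one
  explicitly on a subset.
* **Run rules.** Rule 1 (point outside its limits) is always active. A shift
  rule (8 consecutive points strictly one side of the center; points exactly
  on the center break the run, for deterministic evaluation) and a trend rule
  (6 strictly monotone points; ties reset the run) are off by default and
  flagged at every period where the qualifying run is complete.
* **\(\sigma_z = 0\)** (identical z-scores) and **\(\bar u = 0\)** (no events
  anywhere) are legal: the former gives degenerate limits equal to the center,
  the latter makes \(\sigma_z\) undefined and is returned as `NA` rather than
  an error, since an empty surveillance window is a real state of the world.

## The Near Miss Index

Each near miss is scored on a four-point ordinal scale — the worst reasonable
outcome had it not been intercepted — and the index is the weighted tally

\[ \mathrm{NMI} = \sum_{\text{class}} w_{\text{class}} \, n_{\text{class}},
   \qquad w = (1, 2, 3, 5). \]

The weights are the consequence axis of the Severity Assessment Code matrix
collapsed to one dimension; the full likelihood-by-consequence grid is not
used because a near miss's likelihood arm is the event that already happened.
Custom weight tables are accepted but must be strictly increasing — a
non-monotone table silently inverts the prioritization the index exists for.

Events without a severity class are **excluded and counted separately**, never
scored zero: an unscored catastrophic-potential event deflating the index is
the exact failure mode severity weighting is meant to prevent. The index is
reported raw; `nmi_per_exposure()` optionally normalizes per 1000 patient-days
for cross-period comparison. A two-rater Cohen's kappa (`severity_kappa()`)
is included because the index is only as reliable as the scoring.

## Learning yields

Two process metrics quantify the learning loop, not harm reduction:

* **Yield-90** — share of near misses with at least one corrective action
  implemented within 90 days of reporting. Event-denominated; a near miss
  with several actions counts once. The clock starts at the action record's
  report date.
* **Yield-180** — share of implemented actions verified sustained at the
  180-day mark, with objective evidence (process audit or post-implementation
  performance data). Action-denominated.

A verification is accepted from **173 days** after implementation: the
180-day mark minus a 7-day grace, because sustainment audits are scheduled in
weekly cycles and a rigid 180 would fail an audit run on day 178 on timing
alone. Windows that have not closed by the evaluation date are computed and
flagged `provisional` rather than suppressed — dashboards need the early read,
governance needs the caveat. Empty denominators give a typed undefined value
(`NA`), never a division error.

## The interpretation matrix

Five recurrent joint patterns of near-miss, harm, and total-reporting trends
are encoded as a pure function of four inputs (three trend labels plus an
SPC-signal flag), 54 cells in all. Rows are tested in a fixed precedence
order with the riskiest misread first:

1. near misses **and** harm both decreasing → *disengagement risk*
   (reporting fatigue masquerading as improvement);
2. both flat with no SPC signal → *equilibrium*;
3. near misses and overall reporting both increasing → *culture + strain*;
4. near misses increasing while harm is not → *interception improved*;
5. near misses increasing with reporting flat → *detection improved*.

Anything else is `unclassified` with the full diagnostic checklist attached.
Two cells deserve comment. Under this precedence, row 5 is reachable only
when harm is *increasing* while reporting stays flat — the package treats a
flat reporting total with rising near misses and rising harm as a detection
story worth investigating, which is the row's intent. The remaining
both-rising cell (near misses and harm up, reporting down) matches no row and
is escalated as `unclassified` with an explicit "investigate harm rise"
diagnostic: inventing a sixth interpretation would overstate what the matrix
supports. The engine's interpretation and action strings are emitted verbatim
from the row templates so that governance language stays stable across sites,
and the precedence trace is part of the output for auditability.

**Trend labels** default to the sign of the least-squares slope on the period
index, declared *flat* when the fitted total change over the window,
\(|\hat\beta| \times T\), is under 10% of the series mean (ε = 0.10,
configurable). A governance review does not care about drifts smaller than a
tenth of the running level; ε is the one knob users most plausibly retune.
An SPC-run-based labeling (shift/trend rules) is available as an alternative
method. Four periods is the floor for any trend call.

## The synthetic generator

`generate()` emulates the statistical structure the framework assumes:
monthly near-miss and harm counts Poisson at
`rate/1000 × exposure`, with optional gamma-Poisson overdispersion — the
monthly mean is multiplied by a gamma variate with mean 1 and variance equal
to the `dispersion` parameter (the squared coefficient of variation of the
latent rate), giving negative-binomial counts marginally. This is exactly the
mechanism the Laney adjustment exists to absorb, which makes the generator an
honest test bed for the chart selector. Severities are multinomial; each near
miss yields an implemented action with probability `p_action_90`
(implementation lag uniform on 1–90 days) and each implemented action is
sustained with probability `p_sustain_180` (audit at 180+0–13 days).

Defaults mirror the demonstration scenario: 50,000 patient-days per quarter
(16,667/month), true near-miss rate 0.2 and harm rate 1.0 per 1000
patient-days, severity mix 0.5/0.3/0.1/0.1, action probability 0.3,
sustainment probability 2/3. Where a quantity had no stated value (the
severity mix's interpretation as probabilities, detection-mode frequencies of
0.6/0.2/0.1/0.1 with human detection dominant, uniform event dates within the
month), a single realistic choice was made and fixed.

What the generator deliberately does **not** emulate: seasonality and
weekday structure, reporting-culture dynamics (fear, workload, campaign
effects), under-ascertainment drift, and case-mix change. Passing tests on
synthetic data therefore demonstrate that the *analytics* are correct under
the framework's own statistical assumptions — they say nothing about whether
a real hospital's reporting stream satisfies those assumptions, which is
precisely the question the triangulation diagnostics hand back to the user.

`worked_example()` is a separate, fully deterministic fixture: one quarter,
50,000 patient-days, 50 harmful incidents and 10 near misses with severity
tally 5/3/1/1 assigned positionally, 3 actions implemented within 90 days,
2 sustained. It exercises every level-3 output with no randomness at all:

```{r}
fx <- worked_example()
run_level3(fx$events, fx$exposures, fx$actions, as_of = "2025-12-31")
```

## Numerical and validation choices

* Rates, limits and the index are exact arithmetic on doubles; the only
  tolerance anywhere is the trend flatness ε.
* Period labels (`YYYY-MM`, `YYYY-Qn`) sort lexically, so ordering never
  depends on locale or date parsing.
* Chart construction is a pure function of `(counts, denominators)`:
  relabeling periods changes nothing but labels, and identical inputs
  reproduce identical charts byte for byte. Pipeline artifacts are
  deterministic; wall-clock metadata is isolated in `run_meta.json`.
* Validation problem sizes: the dispersion calibration and rate-recovery
  properties are checked on 500-month simulations at 25,000–50,000
  patient-days per month (about 1,600–5,000 events), where the sampling error
  of the empirical rate is under 2% and of \(\sigma_z\) a few percent — large
  enough that the checks test the method, small enough to run in seconds.
  Closed-form oracle comparisons use 20 random short series at relative
  tolerance 1e-12 and 100 random event sets for the index.

## Limitations

The package analyzes *reported* events. Voluntary reporting captures a small,
culturally filtered fraction of true incidents, and nothing here corrects for
under-ascertainment — the interpretation matrix exists precisely because the
numerator is socially produced. Denominator quality is assumed; errors in
patient-day or dose counts pass straight through to the rates. Learning
yields measure responsiveness and persistence of corrective action, not
effectiveness at reducing harm. And the interpretation matrix is decision
support, not inference: its outputs are hedged readings to be weighed with
culture-survey scores and local knowledge, never causal claims.
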