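---
title: "A desk-scale perioperative data warehouse: models, conventions and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{A desk-scale perioperative data warehouse}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(periopdw)
library(data.table)
```

## The problem

Anesthesia information management systems (AIMS) record the operating room
at high resolution — one measurement roughly every 30 seconds for signals
such as heart rate or arterial pressure, plus drug administrations and the
milestones of the anesthesia and surgery procedure. Hospital-discharge
reporting (PMSI-style) describes the same patients at day resolution:
stays, unit stays, ICD-10 diagnoses, CCAM procedure codes. Reusing these
data for research requires a warehouse that links the two worlds, cleans
and quality-flags what the monitors and users produced, derives workable
variables from the raw signals (hypotension burden rather than ten
thousand pressure samples), and serves analysis-ready cohort tables.

`periopdw` implements that chain end to end at desk scale, with a synthetic
source generator in place of the hospital systems so that every stage is
testable against known ground truth.

## Synthetic sources and what they do and do not emulate

`generate_bundle()` emits the full set of source extracts: AIMS-side
patients, interventions (operating-room windows on a fixed 30 s grid),
vital-sign series, drug and step events; PMSI-side stays, unit stays,
diagnoses and procedures; biology results; a mortality registry. Timestamps
are second-resolution UTC, stay dates day-resolution, and intervals are
half-open `[start, end)` throughout.

Vitals are modeled as a per-signal baseline plus AR(1) noise clipped to
physiological bounds (MAP 85 mmHg, HR 75 bpm, SpO2 98 %, and so on — see
`signal_catalog()`). AR(1) is the simplest process with realistic
autocorrelation; it reproduces the feature that matters for episode
detection — values drift smoothly rather than jumping independently — and
nothing else. The generator does **not** emulate pharmacokinetics,
waveform-resolution physiology, correlated multi-signal dynamics
(SBP/DBP/MAP are simulated independently), French label conventions, or
realistic diagnosis/procedure co-occurrence. Passing tests therefore
demonstrate correctness of the *pipeline mechanics* on data with the right
shape, cadence and failure modes — not clinical validity of any threshold.

Episodes are injected as contiguous excursions strictly beyond a stated
threshold, with the excursion depth drawn per episode and the duration a
multiple of the 30 s step. Two design guarantees make ground truth
exhaustive, both deliberate: background samples of a signal under an
episode specification are clipped a 2-unit guard band onto the safe side of
the threshold, so every crossing in the emitted series is an injected one;
and episodes are separated from each other and from window edges by at
least two samples, so detected runs never merge. The truth log records each
episode's half-open window exactly.

`corrupt_bundle()` injects the defects the transform step exists to catch:
lost measurement identifiers, drug doses re-expressed in grams (the value
divided by 1000, as happens when two units coexist for one drug),
implausible values, misspelled step-event labels beyond what normalization
can repair, monitor-brand signal-code variants (`MAP-GE`, `MAP-Mindray`),
and stays whose dates no longer contain their operating-room date. Rates
below 1 are fractions of eligible rows; integer values are exact counts,
which keeps count-exact assertions simple. Each row is corrupted at most
once, and date-shifted stays are chosen so no sibling stay accidentally
covers the intervention — otherwise the discordance would be undetectable
in principle and the ground-truth count wrong by construction.

## Transform rules

*Vocabulary.* Labels are normalized (trim, collapse whitespace, case-fold,
strip diacritics) and then mapped through a synonym table; an unmapped
normalized label becomes its own canonical form. Brand variants of the same
signal collapse to one code this way.

*Units.* Conversion rules are single-step (`g -> mg` ×1000); chained or
ambiguous rule sets are configuration errors. Unknown units are left
untouched — flagging, not conversion, is the mechanism that reports them.

*Quality flags.* Every measurement and drug row gets exactly one flag, in
precedence order `orphan` > `missing_value` > `bad_unit` > `out_of_range` >
`ok`, judged against the row *as received*: a dose that arrives in grams
keeps its `bad_unit` flag even though the loaded value is standardized to
milligrams afterwards. The flag documents the source defect; the conversion
repairs the value; features use only `ok` rows.

*Linkage.* An intervention links to a stay of the same patient whose date
interval contains the operating-room entry date. Among several candidates
the latest admission on or before the intervention wins (the most specific
admission — a day-4 admission beats a day-1 admission for a day-5
intervention), with residual ties broken by smallest stay id to stay
deterministic. Unlinkable records are reported with a reason, never
dropped.

## The warehouse and its two loading flows

The warehouse is row-oriented: dimension tables (patient, signal, care
unit, drug, event, code) and fact tables (intervention, measurement, event
record, stay, unit stay, diagnosis, procedure, biology, death), one row per
record, each measurement carrying its quality flag. It lives in memory as
typed tables and persists as a directory of deterministic UTF-8 TSV files
plus a manifest — plain text, diffable, and checksummable, which is exactly
what the idempotence guarantees are stated in terms of (`wh_checksum()`
covers the data tables; the load log and quarantine are audit history and
carry run ids and wall-clock times by design).

Loading follows two incremental sliding-window flows, both overwrite-style
(delete-then-insert on natural keys, strictly inside the window):

* **Flow 1** — low-volume facts the sources may retroactively update:
  stays, unit stays, diagnoses, procedures, deaths, plus the patient
  dimension. Window: one year ending at the run date. Stays anchor on their
  admission date; stay children anchor on their stay's admission.
* **Flow 2** — high-volume, non-updatable operating-room facts:
  interventions, measurements, drug/step events, biology. Window: fourteen
  days. Measurements and events anchor on their own timestamp's date,
  interventions on the room-entry date. The intervention header travels
  with its children here because it is OR-sourced and immutable.

Window discipline is absolute: a flow never inserts, updates or deletes a
row anchored outside its declared window, so weekly runs tile without gaps
or duplicates and re-running on unchanged staging is byte-identical. Rows
without a usable key — e.g. measurements that lost their intervention id —
are quarantined and counted as rejected, and every run's log row satisfies
`rows_in = rows_loaded + rows_rejected`.

## Intraoperative features and the episode model

Between samples, a signal is modeled as a last-observation-carried-forward
(LOCF) step function: the sample at $t_i$ holds until
$\min(t_{i+1},\, t_i + \text{max\_gap},\, \text{period end})$. Maximal
stretches of held time with the value strictly beyond the threshold
($v < T$ for *below*, $v > T$ for *above*) are candidate episodes;
candidates shorter than `min_duration_s` are discarded. Episode burden is
the rectangle sum

$$\text{area} = \sum_i |v_i - T| \cdot \text{held}_i
\quad [\text{signal unit} \times \text{s}],$$

the familiar area-between-curve-and-threshold measure of, for example,
intraoperative hypotension.

Why LOCF rectangles and not interpolation: the step model is honest to
sampled data (it never invents a crossing time between samples), it makes
time-below and area monotone in the threshold, and it is trivially
checkable by a brute-force per-second evaluation — the test suite carries
exactly that oracle, written independently, and requires exact agreement on
30 s grids and ragged subsamples alike.

Defaults, all exposed per feature: `max_gap_s = 300` (a sample's influence
ends after five minutes of silence, so monitor dropouts split episodes
rather than bridging them), `min_duration_s = 60` (one isolated 30 s sample
is noise at this cadence; two consecutive samples are the shortest episode
worth counting). Strict inequality defines "beyond": a value equal to the
threshold is not an excursion, matching the "less than 65 mmHg" phrasing
such thresholds are quoted with. The shipped example thresholds (MAP < 65
and < 50 mmHg, SpO2 < 90 %, HR > 100 and < 45 bpm) are illustrative
configuration, not clinical claims.

Periods of interest are defined from step events (`period_rule()`:
anchor event ± offset on each side), and `extract_features()` computes a
long-form table — one row per intervention, period and feature — using only
`ok`-flagged samples. Interventions whose anchors are missing or duplicated
get null rows with a reason code rather than failing the extraction.

## Datamarts and cohorts

`pivot_features()` turns the long table into a wide one-row-per-unit table
(duplicate (unit, feature) pairs are an error, not a silent overwrite), and
`unpivot_features()` inverts it exactly up to row order. Cohorts are
conjunctive filters over wide-table columns with three-valued logic: a
predicate evaluating to `NA` for a row excludes it, the safe reading of an
inclusion criterion over incomplete data. `cohort_summary()` rounds half-up
to one decimal because that is how such percentages are reported in
clinical tables (base R's round-half-to-even would print 6.2 for 1/16).

## Data quality

Checks are organized on four axes — completeness (required step events per
intervention, values present), correctness (plausible ranges, standard drug
unit, canonical vocabularies), concordance (the operating-room date falls
inside a hospital stay of the same patient), plausibility (discharge after
admission, death after last discharge, room exit after entry) — and run
against either the staged sources or the loaded warehouse without mutating
them. Vocabulary checks only make sense before cleaning and are marked
source-side. Results persist to a history table per run so indicator trends
can be followed load after load; reported failure keys are capped at 50 per
check to keep reports readable. `monitor_loads()` summarizes the load log
and flags any run violating row-count conservation.

## OMOP export

The operating-room passage is exported as a `VISIT_DETAIL` child of its
hospital stay's `VISIT_OCCURRENCE`, exactly like an ICU unit stay; vitals
go to `MEASUREMENT`, drug administrations to `DRUG_EXPOSURE` (point-in-time:
start = end = administration timestamp), step events route by concept-map
domain — Procedure-mapped events to `PROCEDURE_OCCURRENCE`, free-text
milestones to `OBSERVATION` — and coded procedures to
`PROCEDURE_OCCURRENCE` at stay level. Column names follow CDM v5.4. Every
OR-derived row carries a resolvable `visit_detail_id`; an unlinked
intervention is exported under a synthetic standalone visit and counted.

The bundled concept map (`extdata/mini_vocab_synthetic.csv`) is a
constructed stand-in — the production local-to-standard mapping is not
public and the full OHDSI vocabulary is a download this package
deliberately avoids. Labels it does not cover fall back to deterministic
ids in the reserved local range starting at 2,000,000,000 and are counted
in the export report, so conservation is checkable:
ok-flagged warehouse rows = exported rows + counted exclusions, per
category (diagnoses are a counted exclusion; the export targets the OR
record and the visit hierarchy).

## Federated logistic regression

For a logistic model with coefficients $\beta$, center $c$ holding
$(X_c, y_c)$ computes, at a shared $\beta$,

$$g_c = X_c^\top (y_c - \mu_c), \qquad
I_c = X_c^\top W_c X_c, \qquad
\mu = \operatorname{logit}^{-1}(X\beta),\; W = \mathrm{diag}(\mu(1-\mu)).$$

Score and information are sums over rows, so
$\sum_c g_c$ and $\sum_c I_c$ equal the pooled-data quantities *exactly* —
not approximately — and Newton–Raphson on the aggregates follows the
identical iterate path as a centralized fit, for any partition of the rows.
That is the whole point of the proof of concept: the test suite asserts
per-iteration agreement with an independently written pooled Newton loop to
1e-10, and that each single-center Wald interval is at least as wide as the
federated one. Only `center_summary` objects (a count, a $p$-vector, a
$p \times p$ matrix) cross the aggregation boundary; the aggregation
function rejects anything else by construction. No secure-aggregation or
encryption layer is provided or claimed.

Numerics: start at $\beta = 0$, converge when the max-norm of the
aggregated score is at most 1e-8, cap at 25 iterations, no regularization.
Complete separation is surfaced as an explicit error rather than silent
divergence: at a separated "optimum" the score vanishes while the
information collapses toward zero, so the fit checks the smallest
eigenvalue of the aggregated information against an absolute floor
(`sqrt(.Machine$double.eps)`) before inverting it. Confidence intervals are
Wald: $\hat\beta \pm 1.959964\, \widehat{\mathrm{se}}$ at 95 %. The
simulated dataset for the proof of concept (`simulate_logistic_data()`)
uses standard-normal covariates and a stated true coefficient vector; it is
documented as synthetic and does not claim to reproduce any clinical
study's coefficients.

## Problem sizes and numerical conventions

The shipped tests and the acceptance script run the chain at sizes chosen
to exercise every code path while keeping a full run in the tens of
seconds: bundles of 5–50 patients (up to roughly 200,000 measurement rows),
about 50 interventions with about 100 injected MAP < 65 mmHg episodes for
recovery checks, 200 randomized series for the monotonicity property, 100
randomized tables for the pivot round-trip, and n = 400, p = 3, k = 4 for
the federated fit. Determinism is part of every contract: fixed seeds give
byte-identical bundles, warehouse states, and exports.

Degenerate inputs are defined, not accidental: zero usable samples yield
count 0 and null statistics; an empty episode list yields zero counts and a
null nadir; an empty cohort is an empty table with its header; an empty
warehouse exports valid empty CDM files.

## Known limitations

* The generator's realism limits are listed above; in particular, exact
  episode-count recovery relies on the guard band — on real data,
  spontaneous threshold crossings are the signal, not a nuisance, and no
  exact-count guarantee can exist.
* The warehouse store is in-memory tables with TSV persistence: right for
  desk-scale validation, not for production volumes or concurrent writers
  (a single-run guard exists, but there is no locking across processes).
* Linkage uses date containment only; real deployments disambiguate with
  administrative identifiers.
* The OMOP export covers the OR-centric tables; conditions, care sites and
  cost tables are out of scope, and the mini-vocabulary is synthetic.
* Federated fitting covers logistic regression only, with plain (not
  privacy-hardened) summary exchange.
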