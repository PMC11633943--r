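---
title: "icurounds: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{icurounds: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(icurounds)
```

## The problem

Adult ICU care includes a fixed battery of items that should be reviewed
daily on every patient: glycemic safety, venothromboembolism (VTE) and
stress-ulcer prophylaxis (SUP), lung-protective ventilation, sedation
weaning and ventilator-liberation readiness, nutrition, and the ongoing
justification of every indwelling device. A static 23-item checklist per
patient per day is burdensome and invites alarm fatigue; the useful signal
is the *gap* — a metric that is relevant to this patient today and not
currently satisfied. `icurounds` is a dynamic engine for exactly that: each
metric either raises a binary actionable flag with machine-readable reason
codes, or stays silent.

This vignette is the package's own account of the model: the event
semantics, the decision tables, every tunable default and why it is set
where it is, what the synthetic generator emulates, and the limitations.

## Event model and temporal semantics

The engine's only input is a stream of typed clinical events per patient
(eleven kinds: medication orders, MAR administration actions, labs, device
episodes, diagnoses, ventilator observations, nutrition records, code
status, transfusions, activity orders, flowsheet documentation) plus an
evaluation instant. Conventions:

* **Half-open intervals** `[start, end)`, `end` absent meaning *ongoing*.
  Half-openness makes adjacency unambiguous: a device removed at 12:00 and
  replaced at 12:00 yields no overlap and no gap.
* **Timestamps** are ISO-8601 with offset; internally everything is UTC.
  The *current day* runs from local midnight (configurable time zone) to
  the evaluation instant, so day-coverage denominators use **elapsed** time.
  Below a configurable minimum elapsed time (default 4 h) the day-coverage
  rules *abstain* rather than judge prophylaxis coverage on a sliver of a
  day; abstention never raises a flag.
* **Amendments**: events sharing an `event_id` are versions of one record;
  the latest-recorded one wins, mirroring EHR amendment behavior. Assembly
  is therefore deterministic under any permutation or duplication of the
  input rows.
* **Source of truth**: medication questions consult orders and MAR actions
  only. A flowsheet note claiming a drug was given, with no administration
  event behind it, is deliberately invisible to every medication-dependent
  query. Flowsheet documentation still carries what only flowsheets record
  (e.g. liquid-stool output).

The workhorse primitive is `coverage_fraction()`: the measure of the union
of intervals intersected with a window, divided by the window length, with
overlaps merged first so duplicate documentation cannot inflate coverage.

## Missing data

Every rule input declares exactly one of three policies, applied by
`resolve_missing()`:

1. *Expected present, missing* → **negative finding**. A patient expected
   to have chemical VTE prophylaxis with no such order simply does not have
   prophylaxis; the absence itself is the care gap.
2. *Expected absent, missing* → **positive finding**. No central line in a
   patient who does not need one is the goal state; there is nothing to
   act on.
3. *Absent lab* → **assumed within normal limits**, on the premise that
   clinicians actively chose not to obtain it. Substitution values ship in
   `default_config()$normal_labs` (glucose 110 mg/dL, platelets 250 k/µL,
   INR 1.0, aPTT 30 s — unremarkable adult values).

Each resolution is recorded in the result's `inputs_used` audit trail
(`"missing(assumed_normal=1)"` and the like), so a reviewer can see which
branch fired — the same granularity a chart auditor works at. A property
test exercises the power set of absent inputs per rule: every subset yields
a defined, non-crashing result.

A second fail-safe sits above the policies: if an evaluator errors for any
reason, the rule abstains (reason `evaluator_error`) instead of flagging.
A broken rule must not create false actionable alerts, because false
positives are what erode clinician trust in such tools.

## The 23 metrics

The registry ships 23 metrics in 7 categories. The engine's own accounting
is row-per-metric: the combined VTE prompt, both SUP directions, both
nutrition prompts, five removal prompts and four line-risk prompts are each
separately evaluated and separately validated, which is why the count is 23
even though informal summaries of such metric sets often quote "about two
dozen". Only a handful of thresholds are fixed by published rule text; they
are honored with their exact comparators:

| threshold | comparator |
|---|---|
| hypoglycemia | glucose **≤ 70** mg/dL today |
| mechanical-prophylaxis coverage | **≥ 0.75** of the elapsed day |
| coagulopathy | platelets **< 50** k/µL, INR **≥ 1.5**, aPTT **> 40** s, each over a 3-day lookback |
| transfusion exclusion | **> 1** PRBC unit in the prior 24 h blocks the VTE prompt |
| tidal volume | latest Vt / PBW **> 8** mL/kg flags (at or below 8 is protective) |
| nutrition adequacy | delivered **< 0.80** × goal kcal over the prior 24 h; exactly 80 % is met |

Everything else is a **declared, config-overridable default**, modeled on
the clinical-practice-guideline framing such engines are built from, and
explicitly not a claim about any particular institution's build:

* *SUP*: risk factors are ongoing mechanical ventilation or coagulopathy;
  start when a risk factor is active without acid suppression, stop when
  suppression runs without a risk factor. Stopping is *not* suppressed by
  comfort-care status — deprescribing aligns with comfort goals — whereas
  every prophylaxis/nutrition/wean prompt is.
* *Sedation wean*: an active sedative infusion with ≥ 6 h administered
  (union) time today, no paralytic, no status epilepticus / intracranial
  hypertension diagnosis.
* *SBT readiness*: intubated, latest FiO₂ ≤ 0.5 and PEEP ≤ 8 cmH₂O, no
  vasopressor administration in 4 h, no paralytic, no trial yet today.
  Undocumented ventilator settings mean *not demonstrably ready* — for a
  screening prompt the conservative direction is silence.
* *Nutrition start*: 48 h post admission with no nutrition record in 48 h.
* *Removal indications*: urinary — retention/obstruction/irrigation
  diagnoses or strict-I/O with an active vasopressor; central — vasopressor
  administration within 12 h, an active central-only infusion order, or
  hemodialysis; arterial — vasopressor within 12 h or ≥ 4 ABGs in 24 h;
  PICC — an active long-course IV therapy indication; rectal — documented
  liquid stool today with a skin-breakdown diagnosis.
* *Line risk*: femoral site at any dwell, or dwell beyond 7 days (central,
  arterial, hemodialysis) / 30 days (PICC).
* *Surveillance culture*: a line placed outside the institution, still in,
  with no blood culture since admission. The flag persists until a culture
  is drawn or the line comes out — a time-capped variant (only within the
  first 48 h) was considered and rejected, since an unscreened outside line
  on day 3 is no safer than on day 1.

Predicted body weight uses the Devine formula (male
`50 + 0.91·(height_cm − 152.4)`, female `45.5 + 0.91·(height_cm − 152.4)`,
floored at zero). Actual weight was deliberately not used: Vt/kg targets in
lung-protective ventilation are defined on predicted, not measured, weight.

Diagnosis matching is by structured code keyword lists only — free-text
clinical reasoning is out of scope by design, because it is exactly the
data source the engine's source-of-truth hierarchy distrusts.

## Validation machinery

`accumulate_confusion()` pairs engine flags with ground-truth labels per
(patient, rule) and tallies TP/FP/TN/FN per rule and overall;
`classification_stats()` derives sensitivity, specificity, accuracy, PPV
and NPV, leaving a statistic `NaN` when its denominator is zero (a metric
that never saw a positive case has no sensitivity). Reporting rounds half
away from zero to three decimals, with trailing zeros truncated
("0.970" → "0.97", "1.000" → "1") — `format_stats()`.

`reconstruct_counts()` inverts that reporting step: given a row total `n`
and at least three printed statistics, it enumerates every non-negative
`(tp, fp, tn, fn)` summing to `n` (≈ n³/6 tuples; under a second at
n ≈ 190) and keeps those whose recomputed statistics round to every printed
value, with a printed `NaN` forcing the corresponding zero denominator.
The uniqueness flag matters: an all-perfect row (every statistic 1) is
inherently under-determined — any split of `n` into tp + tn reproduces it —
whereas one imperfect statistic usually pins the counts down exactly. The
shipped example rows (`inst/extdata/validation_rows.csv`) all round-trip,
and the identifying rows reconstruct uniquely, which also lets a held-out
statistic be recomputed from the other four and compared against its print.

## The synthetic generator

`generate_patient_day(rule_id, actionable, seed)` builds a patient-day
whose ground truth for the chosen metric is exactly the requested label
under the shipped decision tables, while a curated baseline (normal
glucose, an active prophylactic LMWH order, adequate enteral nutrition once
48 h post admission, full code, no devices) drives every other metric
non-actionable. One metric is perturbed per patient-day so labels are
unambiguous, mirroring a per-metric chart audit. The single structural
exception is the combined VTE metric: its actionable state (no prophylaxis
modality at all, no exclusions) necessarily makes the mechanical-VTE metric
actionable too, so both labels are emitted truthfully rather than
pretending independence.

`generate_cohort()` draws one metric per patient uniformly and its label
from a per-metric prevalence (default 0.5), then `inject_noise()` adds the
phenomena that make naive chart logic fail: flowsheet notes claiming
medications the MAR never recorded, stray device claims, and deleted labs.
MAR events are never altered — they are the source of truth the engine is
built around, which is why note noise at probability 1.0 changes zero
flags, while lab deletion legitimately reroutes decisions through the
assumed-normal policy without ever crashing.

What the generator does **not** emulate: real demographic or severity
distributions, multi-gap patients, contradictory device documentation,
free-text reasoning, or charting-delay artifacts. A perfect closed loop
(sensitivity = specificity = 1 on generated cohorts) therefore demonstrates
internal consistency of engine and decision tables — it is a correctness
harness, not a claim about accuracy on real charts, where imperfect
documentation is precisely what degrades such tools.

## Numerical and procedural choices

* Problem sizes: the closed-loop check uses a 500-patient census
  (11 500 rule evaluations); oracle equivalence uses 1000 randomized
  scenarios × 23 metrics against an independently coded straight-line
  decision table; coverage is cross-checked against a minute-midpoint grid
  on minute-aligned instances, where the grid is exact.
* Boundaries: comparator directions are taken literally (≤ 70 flags; 0.75
  coverage flags; exactly 80 % adequacy does not). The adequacy comparison
  subtracts 1e-9 before comparing so floating-point delivery sums cannot
  flag a patient fed exactly to goal.
* Ties: equal lab result times resolve to the latest-recorded event; equal
  interval endpoints merge (half-open semantics).
* Seeds: every stochastic path (generator, noise, scenario sampling) is
  seed-threaded; identical seeds give byte-identical artifacts, and RNG
  state is restored after generation.

## Limitations

* 22 of the 23 decision tables are declared defaults, not published rule
  text; deployments are expected to override thresholds and keyword lists
  via the YAML configuration.
* Drug classes and diagnosis codes are assumed pre-mapped; there is no
  terminology service, no HL7/FHIR ingestion, and no free-text processing.
* The engine evaluates; it does not alert, escalate or track
  acknowledgment, and it says nothing about whether flags change clinical
  behavior — that is an evaluation question downstream of this artifact.
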