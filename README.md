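# icurounds

A rule-based clinical decision support engine for the standard quality
metrics that should be reviewed daily on every adult ICU patient.

Critically ill patients accumulate routine care items — VTE and stress-ulcer
prophylaxis, lung-protective tidal volumes, sedation weaning, spontaneous
breathing trials, nutrition adequacy, and the removal of urinary catheters,
central lines, arterial lines, PICCs and rectal tubes — that are easy to miss
on rounds. `icurounds` evaluates **23 daily metrics across 7 categories**
against a typed electronic-health-record event stream and raises a binary
actionable flag ("X" on a census table) only where a gap exists between
active interventions and guideline recommendations, so clinicians attend
only to items that need action.

The package is aimed at clinical informaticists and quality/safety
researchers who need a transparent, auditable, testable reference
implementation of such an engine outside any particular EHR vendor build.

## The engine in brief

Each metric is a pure decision function of a *patient-day context*: one
patient's deduplicated event stream (medication orders, MAR administration
actions, labs, device episodes, diagnoses, ventilator observations,
nutrition records, code status, transfusions, activity orders, flowsheet
documentation) plus an evaluation instant. Three pillars:

* **Temporal queries.** All intervals are half-open `[start, end)`. The core
  primitive is the coverage fraction
  `|union(intervals) ∩ window| / |window|`, which powers criteria such as
  *mechanical VTE prophylaxis in place for ≥ 75 % of the current day*.
  Lab lookbacks (e.g. coagulopathy: platelets < 50 k/µL, INR ≥ 1.5 or
  aPTT > 40 s within 3 days) and dwell times come from the same context.
* **Missing-data semantics.** Every rule input declares one of three
  policies: data *expected but absent* is a negative finding (a missing
  chemoprophylaxis order counts as "no prophylaxis"); data *expected to be
  absent* is a positive finding (no central line means nothing to remove);
  an *absent lab* is assumed within normal limits. Absence can therefore
  never crash a rule, and every resolution is recorded in the result's
  audit trail.
* **Source of truth.** Medication questions are answered from orders and
  MAR actions only; flowsheet notes claiming a drug was given are ignored
  when no administration record exists.

Tidal volume is scaled by Devine predicted body weight
(male `50 + 0.91·(height − 152.4)`, female `45.5 + 0.91·(height − 152.4)` kg),
the lung-protective-ventilation standard. Thresholds and diagnosis keyword
lists ship in a single configuration (`default_config()`), overridable per
deployment from YAML.

The companion validation module accumulates TP/FP/TN/FN confusion counts
against ground-truth labels, derives sensitivity, specificity, accuracy,
PPV and NPV (NaN when a denominator is zero), and — running the reporting
step backwards — exhaustively reconstructs the *integer* confusion counts
behind a published row of rounded statistics (`reconstruct_counts()`),
flagging whether the row pins its counts down uniquely.

A seeded synthetic-EHR generator emits patient-days with per-metric ground
truth and configurable documentation noise, closing the loop
simulate → evaluate → validate entirely in code.

## Worked example

```r
library(icurounds)

pd  <- generate_patient_day("vte_chemical", actionable = TRUE, seed = 7)
ctx <- assemble_patient_day(pd$events, pd$attributes, pd$eval_time)
res <- evaluate_patient_day(ctx)
res[["vte_chemical"]]
#> <rule_result> vte_chemical: X (actionable)
#>   reasons: mech_coverage_ge_75pct, no_chemical_prophylaxis, no_exclusion
str(res[["vte_chemical"]]$inputs_used)
#> List of 9
#>  $ compression_coverage: num 1
#>  $ anticoagulant_active: logi FALSE
#>  $ platelets           : chr "missing(assumed_normal=250)"
#>  $ inr                 : chr "missing(assumed_normal=1)"
#>  $ aptt                : chr "missing(assumed_normal=30)"
#>  $ bleeding_dx         : logi FALSE
#>  $ comfort_care        : logi FALSE
#>  $ prbc_units_24h      : num 0
#>  $ ambulatory          : logi FALSE
```

Reading: this synthetic patient wore compression devices all elapsed day
(coverage 1 ≥ 0.75), has no chemical prophylaxis or therapeutic
anticoagulant ordered, and none of the exclusions apply — coagulation labs
were never drawn, so per the lab policy they are assumed normal (the
`missing(assumed_normal=…)` entries). The engine flags "consider chemical
VTE prophylaxis"; the census cell for this patient shows an `X`.

Inverting a rounded validation summary row (n = 33, sensitivity 1,
specificity 0.966, PPV 0.8, NPV 1):

```r
reconstruct_counts(33, c(sensitivity = 1, specificity = 0.966,
                         ppv = 0.8, npv = 1))
#> $counts
#>   tp fp tn fn
#> 1  4  1 28  0
#> $unique
#> [1] TRUE
```

so that row can only have come from 4 true positives, 1 false positive,
28 true negatives and 0 false negatives — and the held-out accuracy
(4+28)/33 rounds to the printed 0.97.

A command-line wrapper (`inst/cli/icurounds.R`) exposes
`simulate`, `evaluate`, `validate` and `reconstruct` subcommands over the
same functions; see `?cli_main`.

## Vignette

`vignettes/icurounds-methods.Rmd` documents the decision tables, the
missing-data and source-of-truth semantics, every declared default with its
rationale, what the synthetic generator does and does not emulate, and the
package's known limitations.
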