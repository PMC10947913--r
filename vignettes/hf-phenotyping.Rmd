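---
title: "Quality-aware LVEF phenotyping: methods and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quality-aware LVEF phenotyping: methods and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(hfdash)
```

## The problem

Heart failure management programs need to know, for every patient in a
health system, (a) whether the patient has HF at all and (b) which
phenotype — reduced (HFrEF), mildly reduced (HFmrEF) or preserved
(HFpEF) ejection fraction — because guideline-directed therapy differs
by phenotype. The left ventricular ejection fraction (LVEF) that drives
this classification is scattered across sources of very different
reliability: echocardiography reports and clinical notes (free text),
radiology reports (free text, heavily contaminated by nuclear stress
tests and non-cardiac ejection fractions such as gallbladder studies),
and structured catheterization-lab entries where a clinician records a
single LVEF and its source modality. A naive rule — take the lowest
LVEF from any source — inherits every artifact of the worst source and
systematically over-calls HFrEF. This package implements the
quality-aware alternative and the tooling to measure the difference.

## The procedure

1. **Inclusion.** A patient is phenotyped only with documented HF: an
   encounter ICD diagnosis matching the configured code set (default
   prefixes `I50` and `428`) on or before the reference date, or an
   active problem-list HF entry. LVEF evidence without a documented
   diagnosis does not create a cohort member; chart-review experience
   with such patients shows most do not have clinical HF (stage C/D).
2. **Capture.** Free-text reports pass through a deterministic pattern
   extractor (`extract_lvef()`); structured cath-lab rows are taken as
   is. Non-cardiac mentions are dropped outright.
3. **Tiering.** `assign_tier()` maps (provenance, modality, number of
   values) to high / medium / excluded. The mapping is total on its
   documented domain and *fails closed*: an unknown cath-lab modality
   is an error, never a silent guess.
4. **Selection.** `select_effective_lvef()` applies the cascade
   described below and yields a single effective LVEF or an
   `unspecified_*` verdict with an audit trail.
5. **Classification.** `classify_lvef()`: ≤ 40 → HFrEF; in the open
   interval (40, 50) → HFmrEF; ≥ 50 → HFpEF.

### The selection cascade

Within the lookback window (default 3 years, ending at `as_of_date`):

* If any high-tier study exists within the priority window (default 1
  year), the candidate set is the high-tier studies on the most recent
  such date.
* Otherwise the candidate set is the studies on the most recent date in
  the lookback window; if high- and medium-tier studies share that
  date, only the high-tier ones are kept.
* If distinct single-value candidate studies on that date individually
  support both the reduced (≤ 40) and the preserved (≥ 50) class, the
  patient is `unspecified_conflict` — a patient cannot be both HFrEF
  and HFpEF.
* All candidate values then pool. One value is used directly. Several
  go through multi-value resolution: any value > 75 →
  `unspecified_implausible`; spread between the high and low value
  ≤ 10 points → their average; larger spread → the high value alone.

The legacy mode (`select_effective_lvef_v1()`) is the minimum of every
value from every source — excluded tiers included — in the lookback
window, with an ICD-only fallback when no LVEF exists at all.

## Tunable parameters

| Parameter | Default | Units | Why |
|---|---|---|---|
| `lookback_years` | 3 | years | LVEF older than this no longer describes the patient |
| `high_quality_priority_years` | 1 | years | a recent high-quality study should beat anything newer but worse |
| `multi_value_avg_threshold` | 10 | LVEF points | small within-study spreads are measurement noise; average them |
| `implausible_value_threshold` | 75 | LVEF percent | values above this inside a multi-value study are clinically implausible |
| `hfref_max` / `hfmref_max` | 40 / 49 | LVEF percent | guideline phenotype bands |
| `hf_code_prefixes` | `I50`, `428` | ICD prefixes | documented-HF inclusion; both coding eras can appear in a 3-year window |

All of these live in `classification_config()` and can be loaded from
YAML (`read_classification_config()`).

## Design choices where the design was open

* **Window semantics.** "Past year" and "past 3 years" are read as
  calendar anniversaries, inclusive at the old boundary: a study dated
  exactly 3 years before the reference date is in; one day older is
  out. Tests pin both sides of the boundary.
* **Scope of the conflict rule.** The cascade yields candidates on a
  single date, so the HFrEF-vs-HFpEF conflict check applies to
  same-date single-value studies only. Same-date disagreement between
  *adjacent* classes (HFrEF vs HFmrEF) is not a conflict; those values
  flow through multi-value pooling instead. Only the reduced/preserved
  pair is contradictory enough to abstain on.
* **Scope of the > 75% rule.** The implausibility rule is applied only
  inside multi-value resolution, which is the context that motivates
  it (text extraction pulling a spurious second number). A genuine
  single-value LVEF of 80 classifies as HFpEF.
* **≥ 3 pooled values.** "High and low" are read literally as the
  maximum and minimum of the pooled set.
* **Date ties across tiers.** Outside the priority window, when a
  high- and a medium-tier study share the most recent date, the
  high-tier study wins — quality preference is the design's animating
  principle.
* **Qualitative text.** Phrases like "normal LV systolic function"
  yield no numeric mention. Mapping words to numbers would inject an
  unvalidated convention into a numeric algorithm.
* **Legacy ICD-only fallback.** When the legacy mode finds no LVEF it
  maps systolic-HF codes (`I50.2x`, `I50.4x`, `428.2x`, `428.4x`) to
  HFrEF and diastolic (`I50.3x`, `428.3x`) to HFpEF, otherwise
  unspecified. This mapping is a configurable assumption
  (`icd_fallback_map`), not a claim about any production system.
* **GDMT classes and target doses** (beta-blocker, RAAS inhibitor,
  MRA, SGLT2 inhibitor for HFrEF; SGLT2 inhibitor for HFmrEF/HFpEF)
  are guideline-derived editable defaults in `kpi_config()`. The
  high-risk medication lists (NSAIDs, DPP-4 inhibitors alogliptin and
  saxagliptin, thiazolidinediones for any HF; cilostazol, class-I/III
  antiarrhythmics and non-dihydropyridine calcium blockers for HFrEF)
  are fixed per-row testable rules.
* **High-risk patients.** ≥ 2 HF admissions in the past year *and* at
  least one cardiology-specialty encounter in the same window — the
  conjunctive reading; both components are computed separately and can
  be re-weighted in configuration.

## The synthetic cohort generator

`simulate_cohort()` produces gold-labeled cohorts whose noise processes
mirror the failure modes the pipeline exists to survive:

* each patient draws a true phenotype (defaults: 40% HFrEF, 15%
  HFmrEF, 45% HFpEF) and a true integer LVEF uniform inside the class
  band with a 2-point guard off the boundaries, so that noise-free
  recovery must be exact and boundary semantics are tested separately;
* studies are spread over a 4-year timeline across echo text, clinical
  notes, radiology text and structured cath-lab entries;
* nuclear-sourced EFs (cath-lab and radiology) get additive Gaussian
  error, default mean −10, sd 15, clipped to (5, 95) — the direction
  that makes a lowest-value rule over-call HFrEF;
* radiology text is sometimes a gallbladder ejection fraction;
* echo reports sometimes carry two values 1–15 points apart;
* ICD coding is imperfect: some patients lack any HF code, some carry
  non-HF decoy codes.

`sim_preset("clean")` turns all of this off (one recent single-value
echo per patient); `sim_preset("paper_like")` turns it on at the
defaults above. The generator emulates desk-scale structure, not real
clinical language: report texts come from a fixed template bank, there
is no negation or hedging, no inter-reader variability, and coding
noise is independent across patients. Passing tests therefore
demonstrate the algorithm's rule logic, not extraction performance on
production notes.

## Numerical and degenerate-input behavior

Decimal fractions in (0, 1] rescale ×100 and are rounded to 4 decimals
to keep extraction symbolic-exact. Values outside (0, 100] after
rescaling are discarded with a warning. Zero KPI denominators render as
undefined (an em dash), never 0%. Multi-value resolution is symmetric
in argument order. The empty evidence set, the empty cohort and the
empty facility are all first-class inputs with defined outputs.

## Problem sizes used by the checks

The test suite exercises the selection cascade against an independent
brute-force enumeration on 1,000 random evidence sets of up to 6 items,
the extractor on a 200-report fuzz bank, exact recovery on a clean
cohort of 500 patients, and the baseline-vs-hierarchy comparison on a
noisy cohort of 2,000 patients; KPI conservation runs on 50 random
rosters. These sizes give stable stochastic margins while keeping a
full run in minutes on one core.

## Known limitations

* The extractor is a deliberate desk-scale stand-in for a production
  clinical NLP system: no sectionizer, no negation detection, no
  qualitative-to-numeric mapping.
* Stage C/D status is operationalized as documented-HF inclusion; there
  is no symptom model, NYHA class, or stage A/B identification.
* Dose comparison is a numeric ≥ against a configured target; there is
  no claims-grade normalization of units, frequencies or combination
  products.
* Diagnostic-accuracy results on simulated cohorts quantify the
  algorithms' behavior under the generator's assumptions; they are not
  estimates of performance on any real population.
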