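---
title: "Measuring pre-incisional antimicrobial prophylaxis from EMR data"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Measuring pre-incisional antimicrobial prophylaxis from EMR data}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(abxflag)
```

## The measurement problem

Pre-incisional antimicrobial prophylaxis — an antibiotic given before the
skin incision — reduces procedure-related infection substantially and is a
standard quality metric. Unlike most inpatient medications, antimicrobials
given in a procedure room often require no order and generate no
administration record; the evidence that prophylaxis happened may live in a
pre-procedure order placed days earlier at a clinic visit, in a barcode
administration row, or only in the free text of the procedure or anesthesia
note ("cefazolin 1 g IV prior to incision"). Some of that free text exists
only as scanned images of hand-written pages, which no text search can see.

`abxflag` treats the problem as rule-based EMR phenotyping: a procedure is
*flagged* as having documented prophylaxis when any enabled evidence source
fires. The package implements the flagging rules, the evaluation machinery
against gold labels, facility-level stratification, and a synthetic cohort
generator that reproduces the documentation styles and error modes the
method has to contend with.

## Data model and assumptions

Four record roles feed the detector (`emr_cohort()`): procedures, clinical
notes, medication orders, medication administrations. Assumptions baked into
the model:

- **Notes carry a calendar signed date**, not a timestamp; note windowing is
  by day. Orders and administrations carry full timestamps, which the
  same-day post-procedure exclusions need.
- **Timestamps are naive local times** (single-institution assumption); no
  timezone arithmetic is done. Minute resolution.
- **Scanned notes are opaque**: `is_searchable = FALSE` means the text field
  is never matched, whatever it contains.
- A procedure may lack a time of day (`procedure_has_time = FALSE`); see
  *Degenerate inputs* below.

`read_cohort()`/`write_cohort()` round-trip CSV and JSONL losslessly;
malformed rows go to a rejects report instead of being silently dropped.
`dedupe_procedures()` collapses records identical on (patient, datetime,
type) and removes procedures whose type is outside the target set (a
miscoded cardiac catheterization in a device cohort, for instance), with a
per-removal report.

## The lexicon and text matching

The lexicon maps aliases (generic names, brand names, deliberate
misspellings) to canonical agents, with three per-agent attributes that
variants filter on: `oral_only`, `rarely_prophylactic` and
`text_search_excluded`. The shipped default is a guideline-derived list for
cardiac device prophylaxis — cefazolin, cefuroxime, ceftriaxone (first-line
cephalosporins), vancomycin and clindamycin (beta-lactam allergy), plus
cephalexin (`oral_only`) and penicillin (`rarely_prophylactic` and
`text_search_excluded`: it appears in notes overwhelmingly as an allergy
mention). The original national deployment's full search-term list is not
public, so this default is a reconstruction from the same guideline sources;
it is fully overridable via `read_lexicon()`.

Matching decisions, each a genuinely open design point:

- **Whole-word, case-insensitive**: matches are delimited by non-alphanumeric
  boundaries, so "cef" never fires inside an unrelated word. Misspellings
  are covered only by explicit alias variants, not fuzzy matching.
- **Longest alias wins** at a shared offset (so "cefazolin sodium" beats
  "cefazolin"); matches are non-overlapping, ordered by offset (1-based
  character positions, the R convention).
- **No negation or allergy NLP.** The only allergy mitigation is removing
  allergy-prone agents from the text lexicon; an allergy mention of a
  retained agent *will* match. This is a documented limitation, not a bug:
  the flush/wash and allergy scenarios in the synthetic taxonomy exercise
  exactly this behavior.

## Windows and filters

All windows anchor on the procedure date, default `window_days = 7`:
pre-procedure antimicrobials are commonly entered at a visit up to a week
ahead, while widening the window sharply raises the odds of catching an
unrelated treatment course.

- **Notes**: signed date in `[date − w, date]`; the upper bound becomes
  `date − 1` under `exclude_day_of_procedure_notes`. The day-of note is where
  prophylaxis is most often documented, which is why that variant collapses
  sensitivity and is not part of the final algorithm.
- **Orders**: order date in `[date − w, date]` (calendar-day bounds — the
  window is defined on days, and a purely timestamp-based upper bound would
  make the same-day rule below redundant). Three refinement filters:
  `exclude_same_day_post_procedure_orders` drops same-day orders placed
  after the procedure time; `max_order_duration_hours = 24` drops orders
  whose recorded stop time implies a duration of 24 h or more (treatment
  courses, not single prophylactic doses); the agent filters drop
  `oral_only` / `rarely_prophylactic` drugs. Orders *without* a stop time
  pass the duration filter — single pre-incisional doses often lack one, and
  failing them would erase the dominant structured signal; their evidence
  rows carry `stop_missing = TRUE`.
- **Administrations**: within the window and never after the procedure
  timestamp — post-procedural administration is guideline-discordant and
  earns no credit.

Order-side drug matching is exact (normalized) equality of the fielded
`drug_name` against the alias set — orders are structured fields, not prose.
`text_search_excluded` applies only to notes: a penicillin *order* still
counts under a variant without the common-agent restriction.

### Degenerate inputs

When a procedure has no time of day, same-day orders/administrations are
treated as pre-procedure by default (`same_day_policy = "include"`), with
`"exclude"` available to treat them as indeterminate. Empty cohorts, empty
note texts and variants whose filters empty the lexicon are all defined:
the first two yield empty results, the last is an explicit error. Metrics
with zero denominators are reported as `NA` (undefined), never silently 0
or 1.

## Evaluation

`confusion()` requires exactly one gold label per classified procedure and
enforces conservation (tp + fn = gold positives, tn + fp = gold negatives).
`compute_metrics()` yields sensitivity, specificity, PPV, NPV, flagged count
and flagged fraction. `variant_sweep()` evaluates a named set of variants on
one labeled cohort; `stratify_by_facility()` computes per-facility
compliance rates for facilities with at least `min_volume = 50` procedures,
banded `high` (> 80%), `middle` (60–80%) or `low` (< 60%). Both band
boundaries are assigned to `middle` (closed interval) — the verbal
definitions ("greater than 80", "between 60 and 80", "below 60") leave the
endpoints open, and the closed-middle reading is the conservative one for
both neighboring bands.

### The bundled worked-example counts

Real development and validation EMR extracts cannot be redistributed, so the
per-variant confusion counts of the original cohorts ship as fixtures
(`development_counts()`, n = 2102 with 2056 gold-positive;
`validation_counts()`, n = 18,903 with a 50/50 stratified review). Three
reporting quirks in the source grid are worth documenting:

- The development grid's counts for the final source combination imply a
  29 FP / 37 FN split, while the accompanying narrative reports 27 FP /
  39 FN; both sum to 66 misclassified (3.14%). The fixture follows the grid.
- Two grid cells are arithmetically inconsistent with their own numerators
  and denominators (one PPV denominator, one NPV percentage); the fixture
  stores the counts and recomputes all percentages from them.
- The validation "sensitivity" (48/50) and "specificity" (10/50) are
  computed within the flag strata of the review sample, because the sample
  was drawn conditional on the flag; strictly they are the review-sample
  PPV and NPV. The package reproduces them as defined.
- The headline "correctly classified 97.4%" of the development cohort equals
  the flagged fraction (2048/2102), not the accuracy (tp + tn = 2036); the
  package reports it as the flagged fraction.

## The synthetic cohort generator

`generate_cohort()` emulates *documentation*, not disease: each case is one
of 14 scenarios (`scenario_catalog()`) with a known gold label and a
deterministic expected outcome under the final variant — clean typed notes
(TP), order-only documentation (TP through the order source), notes that say
antibiotics were given without naming one (FN), scanned hand-written records
(FN), late-signed notes (FN), stale orders placed 8–60 days ahead (FN),
wrong recorded procedure dates (FN), miscoded procedure types (excluded by
dedup), true negatives with and without any documentation, post-procedure
dose mentions (FP), unrelated long-course treatment (FP), pocket flush/wash
use (FP) and penicillin-allergy mentions (TN under the final lexicon).

Defaults are the generator's definition of the study conditions: prevalence
0.978 (the development-cohort prevalence), a positive mix dominated by
clean-note (0.85) and order-only (0.08) documentation with the error modes
spread thinly (0.01–0.02 each), and a negative mix spread across the
false-positive and true-negative modes. The scenario *frequencies* outside
the discordant subset are not knowable from the source material, so these
defaults are illustrative, chosen once as plausible for a well-documented
system, and the expected-confusion machinery (`expected_confusion()`) is
exact for any mix you specify. `facility_effects` can force all positives at
a facility into one scenario — a "paper-notes facility" whose positives are
all scanned reproduces the low-compliance-band mechanism qualitatively.

Note text is built from templates with randomized filler sentences so that
matching is nontrivial; drug mentions are drawn from the active lexicon. One
RNG stream is seeded once per cohort and consumed in fixed per-case order,
so generation is byte-deterministic in the seed, and the caller's RNG state
is saved and restored.

What the generator does **not** emulate — and therefore what passing tests
do not establish about real data: realistic clinical language (templates are
short and stylized), negation-rich prose, longitudinal patient histories
beyond the peri-procedural window, inter-facility documentation drift beyond
the single forced-scenario mechanism, and the true real-world mix of error
modes. Green tests show the rules behave as specified on the taxonomy, not
that the taxonomy exhausts reality.

## Verification strategy and problem sizes

The test suite checks every operation against independent oracles: a
brute-force per-position substring scan for the matcher, set comprehensions
for the lexicon filters, group-by tallies for dedup, confusion and facility
stratification, and per-source recomputation for the cohort classifier. The
algebraic properties — OR-monotonicity of sources, anti-monotonicity of each
refinement filter, window monotonicity, scanned-note blindness, permutation
invariance, seed determinism — run as property-style loops over generated
cohorts at fixed seeds. Scenario fidelity is exhaustive over the taxonomy
(every scenario as a single-case cohort, several seeds each). Monte-Carlo
recovery compares empirical to analytic confusion within three binomial
standard errors per cell on a 5000-case cohort; unit tests use 150–1000
cases and the acceptance script 5000, sizes at which the binomial bounds are
already tight enough to detect any systematic scenario misclassification.

## Known limitations

- Allergy or negated mentions of retained agents are false positives by
  design; only lexicon curation mitigates them.
- Scanned documentation is invisible; facilities relying on it will show
  spuriously low compliance (hence the banded facility report rather than a
  single pooled rate).
- The 7-day window misses legitimately early orders (rescheduled
  procedures); widening it trades false negatives for false positives.
- The shipped lexicon is a reconstruction and should be reviewed, and
  extended with local formulary names, before use on real extracts.
- Metrics carry no uncertainty intervals; the evaluation module reports
  point estimates only.
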