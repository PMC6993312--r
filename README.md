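# abxflag

Electronic measurement of compliance with **pre-incisional antimicrobial
prophylaxis** from EMR extracts.

Antimicrobials given before a procedure's incision prevent surgical-site and
device infections, and compliance with prophylaxis guidelines is a core
quality metric. Measuring it is hard because operating-room antimicrobials
often require no order: the only trace may be a pre-procedure order placed
days earlier, a barcode administration record, or a sentence in the
procedure or anesthesia note. `abxflag` implements a rule-based phenotyping
algorithm that combines **structured data** (computerized-order-entry
antimicrobial orders, barcode administrations) with **unstructured data**
(lexicon-driven text searches of typed clinical notes) to flag, per
procedure, whether guideline-concordant pre-incisional prophylaxis was
documented. It is aimed at clinical informaticists and quality-measurement
teams who want to replace manual chart review for this metric, and was
designed around cardiac device (CIED) implantation procedures.

## The algorithm

For procedure *i* at datetime *t*, with a look-back window of *w* days
(default 7):

- **text hit** — some searchable (typed, not scanned) note for the patient,
  signed within `[date(t) − w, date(t)]`, contains a whole-word,
  case-insensitive match of an antimicrobial alias (generic names, brand
  names, misspelling variants) from the active lexicon;
- **order hit** — some antimicrobial order for the patient is placed within
  the window, names a filter-surviving agent, runs < 24 h when a stop time
  is recorded, and is not placed after the procedure time on the procedure
  day;
- **admin hit** — some barcode administration of a filter-surviving agent
  falls within the window and not after the procedure;
- **flag** = OR of the hits of the sources enabled in the active
  *algorithm variant*.

The refined (final) variant uses text + orders, excludes oral-only agents
and agents rarely used for prophylaxis, and drops penicillin from the text
lexicon (it appears in notes overwhelmingly as an allergy). All of these
choices are configurable through `algorithm_variant()`; `variant_presets()`
names every development-stage configuration and `final_variant()` is the
refined algorithm.

Because real EMR extracts cannot be redistributed, the package also ships a
**synthetic cohort generator** (`generate_cohort()`) built on a taxonomy of
14 documentation scenarios (clean typed notes, order-only documentation,
scanned hand-written notes, stale orders, post-procedure mentions,
flush/wash use, allergy mentions, ...) with ground-truth labels and known
expected outcomes, plus the per-variant confusion counts of the original
development (n = 2102) and validation (n = 18,903) cohorts as worked-example
fixtures (`development_counts()`, `validation_counts()`).

## Worked example

```r
library(abxflag)
lex <- default_lexicon()
co  <- dedupe_procedures(generate_cohort(cohort_spec(n_procedures = 500, seed = 1)))
res <- classify_cohort(co, lex, final_variant())
res[1:3, 1:6]
#> # A tibble: 3 × 6
#>   procedure_id text_hit order_hit admin_hit final_flag evidence_count
#> 1 PR00001      FALSE    TRUE      FALSE     TRUE                    1
#> 2 PR00002      FALSE    FALSE     FALSE     FALSE                   0
#> 3 PR00003      TRUE     TRUE      FALSE     TRUE                    2

compute_metrics(confusion(res, co$labels))
#> <abx_metrics> n = 500 ( 491 gold+,  9 gold-)
#>   flagged:     457 (91.4%)
#>   sensitivity: 92.9%  specificity: 88.9%
#>   PPV:         99.8%  NPV:         18.6%
```

`PR00001` is an "order-only" case: the note says antibiotics were given but
never names the drug, so only the order source fires — exactly the
documentation style that motivates combining sources. The false negatives
here are the generator's scanned-note / stale-order / late-note error modes,
which the algorithm cannot see by construction.

Facility-level stratification (volume ≥ 50) bands compliance as
`high` (> 80%), `middle` (60–80%) or `low` (< 60%); a `low` band flags
facilities whose documentation practice (e.g. scanned hand-written notes)
defeats electronic measurement:

```r
stratify_by_facility(res, co, min_volume = 50)
#>   facility_id n_procedures n_flagged compliance_rate band
#> 1 F01                  105        97           0.924 high
#> ...
```

The development-grid arithmetic reproduces the published performance of
every variant from the bundled confusion counts, e.g.:

```r
development_grid()[c(4, 9), ]
#>         variant flagged flagged_pct   ppv   npv sensitivity specificity
#> 1   text_orders    2048        97.4 0.986 0.315       0.982       0.370
#> 2 common_agents    2044        97.2 0.987 0.328       0.981       0.413
```

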