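Package: abxflag
Title: Electronic Measurement of Pre-Incisional Antimicrobial Prophylaxis from EMR Data
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Rule-based phenotyping of pre-incisional antimicrobial prophylaxis
    from electronic medical record (EMR) extracts. Combines lexicon-based text
    searches of clinical notes with temporally filtered structured medication
    orders and administrations to flag, per procedure, whether guideline-
    concordant prophylaxis was documented. Includes the evaluation machinery
    (confusion counts, sensitivity/specificity/PPV/NPV, variant sweeps,
    facility-level compliance stratification) and a synthetic EMR cohort
    generator with ground-truth labels and a documented error-mode taxonomy so
    the whole pipeline is testable without real patient data.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    tibble,
    dplyr,
    rlang,
    jsonlite,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
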