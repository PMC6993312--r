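# Synthetic EMR cohort generator. Each generated case is an instance of a
# documentation scenario from a fixed taxonomy of the ways pre-incisional
# prophylaxis does (or does not) leave traces in an EMR: clean typed notes,
# order-only documentation, scanned hand-written notes, stale or post-
# procedure orders, flush/wash and allergy mentions, and so on. Every
# scenario has a known gold label and a deterministic expected outcome under
# the final algorithm variant, which makes the whole detection pipeline
# testable end-to-end without real patient data.

#' The synthetic documentation-scenario taxonomy
#'
#' Each row is one documentation style/error mode observed around procedural
#' antimicrobial prophylaxis, with its ground-truth label and the outcome the
#' final algorithm variant deterministically produces on a case of that kind
#' (`TP`/`FP`/`TN`/`FN`, or `EXCLUDED` for the miscoded-procedure-type case
#' that cohort deduplication removes before classification).
#'
#' @return A tibble: `scenario_id`, `gold_label`, `expected_outcome`,
#'   `description`.
#' @export
scenario_catalog <- function() {
  tibble::tribble(
    ~scenario_id, ~gold_label, ~expected_outcome, ~description,
    "clean_note", TRUE, "TP",
      "drug name typed in a searchable pre/peri-procedure note",
    "order_only", TRUE, "TP",
      "note says antibiotics given without naming the drug; short pre-procedure order present",
    "no_name_no_order", TRUE, "FN",
      "note says antibiotics given; no drug name anywhere, no order",
    "scanned_note", TRUE, "FN",
      "drug name only in a scanned (non-searchable) paper note",
    "late_note", TRUE, "FN",
      "procedure note signed one or more days after the procedure date",
    "stale_order", TRUE, "FN",
      "order placed more than 7 days before the procedure; no drug name in notes",
    "wrong_date", TRUE, "FN",
      "recorded procedure date wrong, so documentation falls outside the window",
    "wrong_type", TRUE, "EXCLUDED",
      "procedure miscoded as a non-device procedure; removed by deduplication",
    "no_documentation", FALSE, "TN",
      "no antimicrobial documentation anywhere",
    "true_no_prophylaxis", FALSE, "TN",
      "notes present but record that no antimicrobial was given",
    "post_procedure_mention", FALSE, "FP",
      "note documents post-procedure doses of a named agent; none pre-incision",
    "unrelated_treatment", FALSE, "FP",
      "patient on a named antimicrobial for an unrelated infection (long-duration order)",
    "flush_wash", FALSE, "FP",
      "agent used only as a pocket flush/wash, named in the note",
    "allergy_mention", FALSE, "TN",
      "penicillin allergy documented; no agent administered"
  )
}

default_mix_positive <- function() {
  c(clean_note = 0.85, order_only = 0.08, no_name_no_order = 0.02,
    scanned_note = 0.02, late_note = 0.01, stale_order = 0.01,
    wrong_date = 0.01)
}

default_mix_negative <- function() {
  c(true_no_prophylaxis = 0.40, no_documentation = 0.15,
    post_procedure_mention = 0.20, unrelated_treatment = 0.10,
    flush_wash = 0.10, allergy_mention = 0.05)
}

#' Specify a synthetic cohort
#'
#' @param n_procedures Number of procedures to generate.
#' @param n_facilities Number of facilities, identified `F01`, `F02`, ...;
#'   cases are assigned uniformly.
#' @param prevalence Proportion of gold-positive cases (default 0.978, the
#'   development-cohort prevalence of appropriately administered prophylaxis).
#' @param scenario_mix_positive,scenario_mix_negative Named probability
#'   vectors over the gold-positive / gold-negative scenarios of
#'   [scenario_catalog()]; each must sum to 1. Defaults put most positives in
#'   `clean_note`/`order_only` and spread the documented error modes thinly,
#'   mirroring the discordant-case review qualitatively.
#' @param facility_effects Optional named list keyed by facility id; each
#'   element a list with `positive_scenario`, forcing every gold-positive
#'   case at that facility into the given scenario (e.g. a "paper-notes
#'   facility" where all positives are `scanned_note`).
#' @param seed Integer seed; generation is byte-deterministic given the spec.
#' @return An object of class `abx_cohort_spec`.
#' @export
cohort_spec <- function(n_procedures,
                        n_facilities = 5,
                        prevalence = 0.978,
                        scenario_mix_positive = default_mix_positive(),
                        scenario_mix_negative = default_mix_negative(),
                        facility_effects = NULL,
                        seed = 1L) {
  cat_tab <- scenario_catalog()
  check_mix <- function(mix, positive, what) {
    if (length(mix) == 0 || is.null(names(mix)) || any(!nzchar(names(mix)))) {
      abort_abx(paste0(what, " must be a named probability vector"),
                "abx_validation_error")
    }
    allowed <- cat_tab$scenario_id[cat_tab$gold_label == positive]
    bad <- setdiff(names(mix), allowed)
    if (length(bad)) {
      abort_abx(paste0(what, " has unknown/off-stratum scenario(s): ",
                       paste(bad, collapse = ", ")), "abx_validation_error")
    }
    if (any(mix < 0) || abs(sum(mix) - 1) > 1e-8) {
      abort_abx(paste0(what, " must be non-negative and sum to 1"),
                "abx_validation_error")
    }
    mix
  }
  if (is.na(prevalence) || prevalence < 0 || prevalence > 1) {
    abort_abx("prevalence must be in [0, 1]", "abx_validation_error")
  }
  n_procedures <- as.integer(n_procedures)
  if (is.na(n_procedures) || n_procedures < 0) {
    abort_abx("n_procedures must be a non-negative integer",
              "abx_validation_error")
  }
  if (!is.null(facility_effects)) {
    facs <- sprintf("F%02d", seq_len(n_facilities))
    bad <- setdiff(names(facility_effects), facs)
    if (length(bad)) {
      abort_abx(paste0("facility_effects names unknown facility: ",
                       paste(bad, collapse = ", ")), "abx_validation_error")
    }
    for (fe in facility_effects) {
      check_mix(stats::setNames(1, fe$positive_scenario), TRUE,
                "facility_effects positive_scenario")
    }
  }
  structure(list(
    n_procedures = n_procedures,
    n_facilities = as.integer(n_facilities),
    prevalence = prevalence,
    scenario_mix_positive = check_mix(scenario_mix_positive, TRUE,
                                      "scenario_mix_positive"),
    scenario_mix_negative = check_mix(scenario_mix_negative, FALSE,
                                      "scenario_mix_negative"),
    facility_effects = facility_effects,
    seed = as.integer(seed)
  ), class = "abx_cohort_spec")
}

# text-building blocks: randomized filler so matching is nontrivial
filler_pre <- c(
  "Patient arrived in the EP lab in stable condition.",
  "Consent reviewed and confirmed.",
  "Site prepped and draped in the usual sterile fashion.",
  "Pre-procedure timeout performed.",
  "Vital signs stable throughout.")
filler_post <- c(
  "Hemostasis achieved; patient to recovery in stable condition.",
  "No immediate complications.",
  "Wound dressed; post-procedure instructions given.",
  "Patient tolerated the procedure well.")

pick <- function(v) v[sample.int(length(v), 1L)]
rint <- function(lo, hi) lo + sample.int(hi - lo + 1L, 1L) - 1L

#' Generate a synthetic EMR cohort
#'
#' Instantiates `spec$n_procedures` cases, each an independent draw of
#' facility, gold label (Bernoulli at `prevalence`) and scenario (from the
#' label's mix, subject to facility effects), and emits the corresponding
#' procedure/note/order/administration records with date arithmetic honoring
#' each scenario's definition (e.g. stale orders are placed 8–60 days before
#' the procedure). Drug mentions are drawn from the active lexicon.
#' Generation is deterministic for a fixed spec: one pseudo-random stream,
#' seeded once from `spec$seed`, consumed in fixed per-case order; the
#' caller's RNG state is left untouched.
#'
#' @param spec An [cohort_spec()].
#' @param lex Lexicon to draw drug names from (default [default_lexicon()]).
#' @return A labeled `abx_cohort`; per-case annotations (scenario id and gold
#'   label) are attached as the `scenarios` attribute.
#' @export
generate_cohort <- function(spec, lex = default_lexicon()) {
  if (!inherits(spec, "abx_cohort_spec")) {
    abort_abx("spec must be an abx_cohort_spec", "abx_validation_error")
  }
  old_seed <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (is.null(old_seed)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old_seed, envir = globalenv())
  })
  set.seed(spec$seed)

  fv <- final_variant()
  # aliases that fire a text match under the final variant
  text_aliases <- build_matcher(lex, fv)$aliases$alias
  # canonical agent names that survive the structured-data filters
  order_agents <- unique(agent_filter(lex, fv, for_text = FALSE)$canonical_name)
  # an oral-only alias for the post-procedure "then <oral> x 5 days" template
  lex_df <- as.data.frame(lex)
  oral_aliases <- lex_df$alias[lex_df$oral_only]
  if (length(oral_aliases) == 0) oral_aliases <- "an oral agent"

  facilities <- sprintf("F%02d", seq_len(spec$n_facilities))
  n <- spec$n_procedures
  base_date <- as.Date("2016-01-01")

  procs <- vector("list", n); notes <- list(); orders <- list(); admins <- list()
  scen_ids <- character(n); gold <- logical(n)
  nn <- 0L; no <- 0L; na_ <- 0L

  add_note <- function(pid, signed, text, searchable = TRUE) {
    nn <<- nn + 1L
    notes[[nn]] <<- tibble::tibble(
      note_id = sprintf("N%06d", nn), patient_id = pid,
      signed_date = signed, text = text, is_searchable = searchable)
  }
  add_order <- function(pid, drug, start, stop) {
    no <<- no + 1L
    orders[[no]] <<- tibble::tibble(
      order_id = sprintf("O%06d", no), patient_id = pid, drug_name = drug,
      route = "IV", order_datetime = start, stop_datetime = stop)
  }
  add_admin <- function(pid, drug, when) {
    na_ <<- na_ + 1L
    admins[[na_]] <<- tibble::tibble(
      admin_id = sprintf("A%06d", na_), patient_id = pid, drug_name = drug,
      admin_datetime = when)
  }
  hours <- function(h) as.difftime(h, units = "hours")
  days_ <- function(d) as.difftime(d * 24, units = "hours")

  for (i in seq_len(n)) {
    pid <- sprintf("P%05d", i)
    fac <- pick(facilities)
    pd <- base_date + rint(0L, 364L)
    proc_dt <- as.POSIXct(pd, tz = "UTC") + hours(rint(7L, 16L)) +
      as.difftime(rint(0L, 59L), units = "mins")
    is_pos <- stats::runif(1) < spec$prevalence
    mix <- if (is_pos) spec$scenario_mix_positive else spec$scenario_mix_negative
    scen <- pick_weighted(mix)
    eff <- spec$facility_effects[[fac]]
    if (is_pos && !is.null(eff$positive_scenario)) scen <- eff$positive_scenario

    ptype <- "cardiac device"
    if (scen == "clean_note") {
      alias <- pick(text_aliases)
      add_note(pid, pd - rint(0L, 2L),
               paste(pick(filler_pre),
                     sprintf("%s 1 g IV administered prior to incision.",
                             alias),
                     pick(filler_post)))
      if (stats::runif(1) < 0.5) {
        start <- proc_dt - hours(rint(1L, 100L))
        add_order(pid, pick(order_agents), start, start + hours(rint(1L, 12L)))
      }
      if (stats::runif(1) < 0.2) {
        add_admin(pid, pick(order_agents), proc_dt - hours(1L))
      }
    } else if (scen == "order_only") {
      add_note(pid, pd,
               paste(pick(filler_pre),
                     "Antibiotics administered prior to incision per protocol.",
                     pick(filler_post)))
      start <- proc_dt - hours(rint(1L, 100L))
      add_order(pid, pick(order_agents), start, start + hours(rint(1L, 23L)))
    } else if (scen == "no_name_no_order") {
      add_note(pid, pd,
               paste(pick(filler_pre),
                     "Antibiotics given prior to incision; see paper chart.",
                     pick(filler_post)))
    } else if (scen == "scanned_note") {
      alias <- pick(text_aliases)
      add_note(pid, pd - rint(0L, 2L),
               sprintf("[scanned image] handwritten anesthesia record: %s 1 g IV pre-incision",
                       alias),
               searchable = FALSE)
    } else if (scen == "late_note") {
      alias <- pick(text_aliases)
      add_note(pid, pd + rint(1L, 3L),
               paste(pick(filler_pre),
                     sprintf("%s 1 g IV was administered prior to incision.",
                             alias),
                     pick(filler_post)))
    } else if (scen == "stale_order") {
      add_note(pid, pd, paste(pick(filler_pre),
                              "Pre-procedure checklist completed.",
                              pick(filler_post)))
      start <- proc_dt - days_(rint(8L, 60L))
      add_order(pid, pick(order_agents), start, start + hours(rint(1L, 12L)))
    } else if (scen == "wrong_date") {
      alias <- pick(text_aliases)
      true_pd <- pd - rint(10L, 20L)   # recorded date is wrong; care happened earlier
      add_note(pid, true_pd,
               paste(pick(filler_pre),
                     sprintf("%s 1 g IV administered prior to incision.",
                             alias),
                     pick(filler_post)))
    } else if (scen == "wrong_type") {
      ptype <- "cardiac catheterization"
      alias <- pick(text_aliases)
      add_note(pid, pd,
               sprintf("%s 1 g IV administered prior to incision.", alias))
    } else if (scen == "no_documentation") {
      # nothing recorded at all
    } else if (scen == "true_no_prophylaxis") {
      add_note(pid, pd,
               paste(pick(filler_pre),
                     "No antimicrobials indicated or administered.",
                     pick(filler_post)))
    } else if (scen == "post_procedure_mention") {
      alias <- pick(text_aliases)
      add_note(pid, pd,
               paste(pick(filler_pre),
                     sprintf("Give %s x 3 doses post-procedure, then %s x 5 days.",
                             alias, pick(oral_aliases)),
                     pick(filler_post)))
    } else if (scen == "unrelated_treatment") {
      alias <- pick(text_aliases)
      add_note(pid, pd - rint(0L, 3L),
               paste(pick(filler_pre),
                     sprintf("Patient continues %s for treatment of bacteremia, day 5 of 14.",
                             alias),
                     pick(filler_post)))
      start <- proc_dt - days_(rint(1L, 5L))
      add_order(pid, pick(order_agents), start, start + days_(7L))
    } else if (scen == "flush_wash") {
      alias <- pick(text_aliases)
      add_note(pid, pd,
               paste(pick(filler_pre),
                     sprintf("Pocket irrigated with %s wash; no systemic antimicrobials administered.",
                             alias),
                     pick(filler_post)))
    } else if (scen == "allergy_mention") {
      add_note(pid, pd - rint(0L, 3L),
               paste(pick(filler_pre),
                     "Allergies: penicillin (rash). No antimicrobials administered.",
                     pick(filler_post)))
    } else {
      abort_abx(paste0("unknown scenario: ", scen), "abx_validation_error")
    }

    procs[[i]] <- tibble::tibble(
      procedure_id = sprintf("PR%05d", i), patient_id = pid,
      facility_id = fac, procedure_datetime = proc_dt,
      procedure_has_time = TRUE, procedure_type = ptype)
    scen_ids[i] <- scen
    gold[i] <- is_pos
  }

  procedures <- if (n > 0) dplyr::bind_rows(procs) else empty_table("procedures")
  labels <- tibble::tibble(
    procedure_id = procedures$procedure_id,
    prophylaxis_given = gold,
    review_source = "synthetic")
  cohort <- emr_cohort(
    procedures = procedures,
    notes = if (nn > 0) dplyr::bind_rows(notes) else empty_table("notes"),
    orders = if (no > 0) dplyr::bind_rows(orders) else empty_table("orders"),
    administrations = if (na_ > 0) dplyr::bind_rows(admins) else
      empty_table("administrations"),
    labels = labels)
  attr(cohort, "scenarios") <- tibble::tibble(
    procedure_id = procedures$procedure_id,
    scenario_id = scen_ids,
    gold_label = gold)
  cohort
}

pick_weighted <- function(mix) {
  if (length(mix) == 1L) return(names(mix))
  names(mix)[sample.int(length(mix), 1L, prob = mix)]
}

#' Analytic expected confusion counts for a cohort spec
#'
#' Linearity of expectation over the scenario taxonomy: each scenario
#' contributes `n * P(gold stratum) * P(scenario | stratum)` cases to its
#' deterministic outcome cell under the final algorithm variant. Facility
#' effects are averaged over the uniform facility assignment. Cases of
#' `EXCLUDED` scenarios are reported separately (deduplication removes them
#' before classification).
#'
#' @param spec An [cohort_spec()].
#' @return A named list of real-valued expectations: `tp`, `fp`, `tn`, `fn`,
#'   `n_excluded`.
#' @export
expected_confusion <- function(spec) {
  cat_tab <- scenario_catalog()
  outcome_of <- stats::setNames(cat_tab$expected_outcome, cat_tab$scenario_id)

  # effective positive mix, averaging facility overrides over the uniform
  # facility draw
  pos_mix <- spec$scenario_mix_positive
  if (!is.null(spec$facility_effects) && length(spec$facility_effects) > 0) {
    w_eff <- length(spec$facility_effects) / spec$n_facilities
    forced <- vapply(spec$facility_effects, function(e) e$positive_scenario,
                     character(1))
    forced_mix <- table(forced) / length(forced)
    all_scen <- union(names(pos_mix), names(forced_mix))
    base <- stats::setNames(numeric(length(all_scen)), all_scen)
    base[names(pos_mix)] <- (1 - w_eff) * pos_mix
    base[names(forced_mix)] <- base[names(forced_mix)] +
      w_eff * as.numeric(forced_mix)
    pos_mix <- base
  }

  cells <- c(TP = 0, FP = 0, TN = 0, FN = 0, EXCLUDED = 0)
  for (s in names(pos_mix)) {
    cells[outcome_of[[s]]] <- cells[outcome_of[[s]]] +
      spec$n_procedures * spec$prevalence * pos_mix[[s]]
  }
  for (s in names(spec$scenario_mix_negative)) {
    cells[outcome_of[[s]]] <- cells[outcome_of[[s]]] +
      spec$n_procedures * (1 - spec$prevalence) * spec$scenario_mix_negative[[s]]
  }
  list(tp = unname(cells["TP"]), fp = unname(cells["FP"]),
       tn = unname(cells["TN"]), fn = unname(cells["FN"]),
       n_excluded = unname(cells["EXCLUDED"]))
}
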