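# Per-procedure flagging logic. A procedure is flagged when any enabled
# source fires:
#   text   — an antimicrobial name (or configured pseudo-term) matched in a
#            searchable note signed within the look-back window;
#   orders — a filter-surviving antimicrobial order placed within the window;
#   admin  — a barcode administration of a filter-surviving agent within the
#            window and not after the procedure.
# Windows are anchored on the procedure date: notes compare calendar days;
# orders use calendar-day bounds with an optional same-day time comparison;
# administrations additionally never count after the procedure time.

window_start <- function(proc_date, variant) proc_date - variant$window_days

#' Text-note flag for one procedure
#'
#' TRUE when at least one searchable note, signed within
#' `[procedure_date - window_days, procedure_date]` (the upper bound becomes
#' `procedure_date - 1` under `exclude_day_of_procedure_notes`), contains a
#' lexicon match. Scanned (`is_searchable = FALSE`) notes are never searched.
#'
#' @param procedure One-row tibble (or list) with `procedure_datetime`,
#'   `patient_id`.
#' @param notes Notes belonging to the procedure's patient.
#' @param matcher An `abx_matcher` from [build_matcher()].
#' @param variant An [algorithm_variant()].
#' @return List with `hit` (logical) and `evidence` (tibble of term matches).
#' @export
flag_text <- function(procedure, notes, matcher, variant) {
  pd <- as_utc_date(procedure$procedure_datetime[[1]])
  upper <- if (variant$exclude_day_of_procedure_notes) pd - 1 else pd
  lower <- window_start(pd, variant)
  keep <- notes$is_searchable &
    notes$signed_date >= lower & notes$signed_date <= upper
  evid <- list()
  idx <- which(keep)
  for (i in idx) {
    m <- match_text(notes$text[i], matcher, source_id = notes$note_id[i])
    if (nrow(m) > 0) evid[[length(evid) + 1L]] <- m
  }
  evid <- if (length(evid)) dplyr::bind_rows(evid) else
    match_text("", matcher)
  list(hit = nrow(evid) > 0, evidence = evid)
}

# alias -> canonical map for structured (order/admin) drug-name matching;
# note text_search_excluded does NOT apply to structured sources
structured_agents <- function(lex, variant) {
  agent_filter(lex, variant, for_text = FALSE)
}

match_drug_name <- function(drug_name, agents) {
  agents$canonical_name[match(normalize_term(drug_name), agents$alias)]
}

#' Medication-order flag for one procedure
#'
#' TRUE when some order satisfies all of: `drug_name` normalizes to a
#' filter-surviving lexicon agent; order date within
#' `[procedure_date - window_days, procedure_date]`; under
#' `exclude_same_day_post_procedure_orders`, a same-day order must not be
#' placed after the procedure time; under `max_order_duration_hours`, an order
#' with a recorded stop time must run strictly less than that many hours
#' (orders with no stop time pass — single pre-incisional doses often lack
#' one; their evidence rows carry `stop_missing = TRUE`).
#'
#' @inheritParams flag_text
#' @param orders Orders belonging to the procedure's patient.
#' @param lex An `abx_lexicon`.
#' @param same_day_policy How to treat same-day orders when the procedure has
#'   no recorded time-of-day: `"include"` (default; treated as pre-procedure)
#'   or `"exclude"` (indeterminate, not counted) — only consulted when
#'   `exclude_same_day_post_procedure_orders` is active.
#' @return List with `hit` and `evidence` (tibble of qualifying orders).
#' @export
flag_orders <- function(procedure, orders, lex, variant,
                        same_day_policy = c("include", "exclude")) {
  same_day_policy <- match.arg(same_day_policy)
  agents <- structured_agents(lex, variant)
  proc_dt <- procedure$procedure_datetime[[1]]
  has_time <- isTRUE(procedure$procedure_has_time[[1]])
  pd <- as_utc_date(proc_dt)

  canon <- match_drug_name(orders$drug_name, agents)
  od <- as_utc_date(orders$order_datetime)
  keep <- !is.na(canon) & od >= window_start(pd, variant) & od <= pd
  if (variant$exclude_same_day_post_procedure_orders) {
    same_day <- keep & od == pd
    if (has_time) {
      keep <- keep & !(same_day & orders$order_datetime > proc_dt)
    } else if (same_day_policy == "exclude") {
      keep <- keep & !same_day
    } # "include": same-day orders treated as pre-procedure
  }
  stop_missing <- is.na(orders$stop_datetime)
  if (!is.null(variant$max_order_duration_hours)) {
    dur_h <- as.numeric(difftime(orders$stop_datetime, orders$order_datetime,
                                 units = "hours"))
    keep <- keep & (stop_missing | dur_h < variant$max_order_duration_hours)
  }
  idx <- which(keep)
  evid <- tibble::tibble(
    order_id = orders$order_id[idx],
    drug_name = orders$drug_name[idx],
    canonical_name = canon[idx],
    order_datetime = orders$order_datetime[idx],
    stop_missing = stop_missing[idx])
  list(hit = length(idx) > 0, evidence = evid)
}

#' Medication-administration flag for one procedure
#'
#' TRUE when some administration of a filter-surviving agent falls within the
#' window and not after the procedure: post-procedural administration is
#' guideline-discordant and earns no prophylaxis credit.
#'
#' @inheritParams flag_orders
#' @param administrations Administrations belonging to the procedure's patient.
#' @return List with `hit` and `evidence`.
#' @export
flag_admin <- function(procedure, administrations, lex, variant,
                       same_day_policy = c("include", "exclude")) {
  same_day_policy <- match.arg(same_day_policy)
  agents <- structured_agents(lex, variant)
  proc_dt <- procedure$procedure_datetime[[1]]
  has_time <- isTRUE(procedure$procedure_has_time[[1]])
  pd <- as_utc_date(proc_dt)

  canon <- match_drug_name(administrations$drug_name, agents)
  ad <- as_utc_date(administrations$admin_datetime)
  keep <- !is.na(canon) & ad >= window_start(pd, variant) & ad <= pd
  if (has_time) {
    keep <- keep & administrations$admin_datetime <= proc_dt
  } else if (same_day_policy == "exclude") {
    keep <- keep & ad < pd
  }
  idx <- which(keep)
  evid <- tibble::tibble(
    admin_id = administrations$admin_id[idx],
    drug_name = administrations$drug_name[idx],
    canonical_name = canon[idx],
    admin_datetime = administrations$admin_datetime[idx])
  list(hit = length(idx) > 0, evidence = evid)
}

#' Classify a single procedure
#'
#' Runs each source enabled in the variant over the records belonging to the
#' procedure's patient; the final flag is the disjunction of the per-source
#' hits. Disabled sources report `FALSE` with empty evidence.
#'
#' @param procedure One-row tibble from `cohort$procedures`.
#' @param cohort An `abx_cohort`.
#' @param lex An `abx_lexicon`.
#' @param variant An [algorithm_variant()].
#' @param matcher Optional precompiled `abx_matcher` (compiled from
#'   `lex`/`variant` when omitted).
#' @param same_day_policy See [flag_orders()].
#' @return A list of class `abx_flag_result`: `procedure_id`, `text_hit`,
#'   `order_hit`, `admin_hit`, `final_flag`, `evidence` (named list of the
#'   per-source evidence tibbles).
#' @export
classify_procedure <- function(procedure, cohort, lex,
                               variant = final_variant(), matcher = NULL,
                               same_day_policy = c("include", "exclude")) {
  same_day_policy <- match.arg(same_day_policy)
  pid <- procedure$patient_id[[1]]
  text_res <- list(hit = FALSE, evidence = NULL)
  order_res <- list(hit = FALSE, evidence = NULL)
  admin_res <- list(hit = FALSE, evidence = NULL)
  if (variant$use_text) {
    if (is.null(matcher)) matcher <- build_matcher(lex, variant)
    nt <- cohort$notes[cohort$notes$patient_id == pid, , drop = FALSE]
    text_res <- flag_text(procedure, nt, matcher, variant)
  }
  if (variant$use_orders) {
    od <- cohort$orders[cohort$orders$patient_id == pid, , drop = FALSE]
    order_res <- flag_orders(procedure, od, lex, variant, same_day_policy)
  }
  if (variant$use_admin) {
    ad <- cohort$administrations[
      cohort$administrations$patient_id == pid, , drop = FALSE]
    admin_res <- flag_admin(procedure, ad, lex, variant, same_day_policy)
  }
  structure(list(
    procedure_id = procedure$procedure_id[[1]],
    text_hit = text_res$hit,
    order_hit = order_res$hit,
    admin_hit = admin_res$hit,
    final_flag = text_res$hit || order_res$hit || admin_res$hit,
    evidence = list(text = text_res$evidence, orders = order_res$evidence,
                    admin = admin_res$evidence)
  ), class = "abx_flag_result")
}

#' Classify every procedure in a cohort
#'
#' Deterministic and order-stable: results are sorted by `procedure_id`
#' regardless of input row order. The matcher and the structured agent filter
#' are compiled once for the whole run.
#'
#' @inheritParams classify_procedure
#' @return A tibble of class `abx_flag_results`: one row per procedure with
#'   `procedure_id`, `text_hit`, `order_hit`, `admin_hit`, `final_flag`,
#'   `evidence_count` and an `evidence` list-column.
#' @export
classify_cohort <- function(cohort, lex, variant = final_variant(),
                            same_day_policy = c("include", "exclude")) {
  same_day_policy <- match.arg(same_day_policy)
  procs <- cohort$procedures
  procs <- procs[order(procs$procedure_id), , drop = FALSE]
  matcher <- if (variant$use_text) build_matcher(lex, variant)

  # pre-split event tables by patient for linear-time lookup
  note_ix <- split(seq_len(nrow(cohort$notes)), cohort$notes$patient_id)
  order_ix <- split(seq_len(nrow(cohort$orders)), cohort$orders$patient_id)
  admin_ix <- split(seq_len(nrow(cohort$administrations)),
                    cohort$administrations$patient_id)

  n <- nrow(procs)
  text_hit <- order_hit <- admin_hit <- logical(n)
  evidence <- vector("list", n)
  for (i in seq_len(n)) {
    prow <- procs[i, , drop = FALSE]
    pid <- prow$patient_id
    tr <- list(hit = FALSE, evidence = NULL)
    orr <- list(hit = FALSE, evidence = NULL)
    ar <- list(hit = FALSE, evidence = NULL)
    if (variant$use_text) {
      nt <- cohort$notes[note_ix[[pid]] %||% integer(), , drop = FALSE]
      tr <- flag_text(prow, nt, matcher, variant)
    }
    if (variant$use_orders) {
      od <- cohort$orders[order_ix[[pid]] %||% integer(), , drop = FALSE]
      orr <- flag_orders(prow, od, lex, variant, same_day_policy)
    }
    if (variant$use_admin) {
      ad <- cohort$administrations[admin_ix[[pid]] %||% integer(), ,
                                   drop = FALSE]
      ar <- flag_admin(prow, ad, lex, variant, same_day_policy)
    }
    text_hit[i] <- tr$hit; order_hit[i] <- orr$hit; admin_hit[i] <- ar$hit
    evidence[[i]] <- list(text = tr$evidence, orders = orr$evidence,
                          admin = ar$evidence)
  }
  out <- tibble::tibble(
    procedure_id = procs$procedure_id,
    text_hit = text_hit, order_hit = order_hit, admin_hit = admin_hit,
    final_flag = text_hit | order_hit | admin_hit,
    evidence_count = vapply(evidence, function(e) {
      sum(vapply(e, function(x) if (is.null(x)) 0L else nrow(x), integer(1)))
    }, integer(1)),
    evidence = evidence)
  class(out) <- c("abx_flag_results", class(out))
  out
}
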