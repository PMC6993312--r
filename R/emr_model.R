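# Four EMR record roles feed the detector: procedures, clinical notes,
# medication orders, medication administrations; plus optional gold labels.
# Notes carry a calendar signed date (note windowing is by day); orders and
# administrations carry full timestamps (needed for the same-day
# post-procedure exclusions). All timestamps are naive local times.

cohort_schemas <- function() {
  list(
    procedures = c("procedure_id", "patient_id", "facility_id",
                   "procedure_datetime", "procedure_type"),
    notes = c("note_id", "patient_id", "signed_date", "text", "is_searchable"),
    orders = c("order_id", "patient_id", "drug_name", "route",
               "order_datetime", "stop_datetime"),
    administrations = c("admin_id", "patient_id", "drug_name",
                        "admin_datetime"),
    labels = c("procedure_id", "prophylaxis_given", "review_source")
  )
}

empty_table <- function(which) {
  switch(which,
    procedures = tibble::tibble(
      procedure_id = character(), patient_id = character(),
      facility_id = character(),
      procedure_datetime = as.POSIXct(character(), tz = "UTC"),
      procedure_has_time = logical(), procedure_type = character()),
    notes = tibble::tibble(
      note_id = character(), patient_id = character(),
      signed_date = as.Date(character()), text = character(),
      is_searchable = logical()),
    orders = tibble::tibble(
      order_id = character(), patient_id = character(),
      drug_name = character(), route = character(),
      order_datetime = as.POSIXct(character(), tz = "UTC"),
      stop_datetime = as.POSIXct(character(), tz = "UTC")),
    administrations = tibble::tibble(
      admin_id = character(), patient_id = character(),
      drug_name = character(), admin_datetime = as.POSIXct(character(), tz = "UTC")),
    labels = tibble::tibble(
      procedure_id = character(), prophylaxis_given = logical(),
      review_source = character())
  )
}

#' Assemble a validated EMR cohort
#'
#' Bundles the four EMR record tables (plus optional gold labels) into one
#' container, enforcing the structural invariants: unique `procedure_id`,
#' order stop times not before start times, at most one label per procedure.
#' Notes, orders and administrations whose `patient_id` does not occur among
#' the cohort's procedure patients are kept but flagged in an `orphan`
#' column.
#'
#' @param procedures Tibble: `procedure_id`, `patient_id`, `facility_id`,
#'   `procedure_datetime` (POSIXct), `procedure_has_time` (logical; FALSE
#'   when only the date is known), `procedure_type`.
#' @param notes Tibble: `note_id`, `patient_id`, `signed_date` (Date),
#'   `text`, `is_searchable` (FALSE for scanned paper/PDF notes, whose text is
#'   treated as opaque and never searched).
#' @param orders Tibble: `order_id`, `patient_id`, `drug_name`, `route`,
#'   `order_datetime`, `stop_datetime` (may be `NA`).
#' @param administrations Tibble: `admin_id`, `patient_id`, `drug_name`,
#'   `admin_datetime`.
#' @param labels Optional tibble: `procedure_id`, `prophylaxis_given`,
#'   `review_source`.
#' @return An object of class `abx_cohort` (a named list of the tables).
#' @export
emr_cohort <- function(procedures = empty_table("procedures"),
                       notes = empty_table("notes"),
                       orders = empty_table("orders"),
                       administrations = empty_table("administrations"),
                       labels = NULL) {
  procedures <- tibble::as_tibble(procedures)
  if (!"procedure_has_time" %in% names(procedures)) {
    procedures$procedure_has_time <- rep(TRUE, nrow(procedures))
  }
  notes <- tibble::as_tibble(notes)
  orders <- tibble::as_tibble(orders)
  administrations <- tibble::as_tibble(administrations)

  for (tb in c("procedures", "notes", "orders", "administrations")) {
    have <- names(get(tb))
    need <- cohort_schemas()[[tb]]
    miss <- setdiff(need, have)
    if (length(miss)) {
      abort_abx(paste0(tb, " missing column(s): ", paste(miss, collapse = ", ")),
                "abx_validation_error")
    }
  }
  dup <- procedures$procedure_id[duplicated(procedures$procedure_id)]
  if (length(dup)) {
    abort_abx(paste0("duplicate procedure_id: ",
                     paste(unique(dup), collapse = ", ")),
              "abx_validation_error")
  }
  bad_stop <- !is.na(orders$stop_datetime) &
    orders$stop_datetime < orders$order_datetime
  if (any(bad_stop)) {
    abort_abx(paste0("order stop_datetime before order_datetime: ",
                     paste(orders$order_id[bad_stop], collapse = ", ")),
              "abx_validation_error")
  }
  if (!is.null(labels)) {
    labels <- tibble::as_tibble(labels)
    miss <- setdiff(cohort_schemas()$labels, names(labels))
    if (length(miss)) {
      abort_abx(paste0("labels missing column(s): ",
                       paste(miss, collapse = ", ")), "abx_validation_error")
    }
    dupl <- labels$procedure_id[duplicated(labels$procedure_id)]
    if (length(dupl)) {
      abort_abx(paste0("multiple labels for procedure_id: ",
                       paste(unique(dupl), collapse = ", ")),
                "abx_validation_error")
    }
  }
  pts <- unique(procedures$patient_id)
  notes$orphan <- !(notes$patient_id %in% pts)
  orders$orphan <- !(orders$patient_id %in% pts)
  administrations$orphan <- !(administrations$patient_id %in% pts)

  structure(list(procedures = procedures, notes = notes, orders = orders,
                 administrations = administrations, labels = labels),
            class = "abx_cohort")
}

#' @export
print.abx_cohort <- function(x, ...) {
  cat("<abx_cohort>\n")
  cat("  procedures:     ", nrow(x$procedures), "\n")
  cat("  notes:          ", nrow(x$notes), "\n")
  cat("  orders:         ", nrow(x$orders), "\n")
  cat("  administrations:", nrow(x$administrations), "\n")
  cat("  labels:         ",
      if (is.null(x$labels)) "none" else nrow(x$labels), "\n")
  rej <- attr(x, "rejects")
  if (!is.null(rej) && nrow(rej) > 0) cat("  rejected rows:  ", nrow(rej), "\n")
  invisible(x)
}

# ---- file I/O ---------------------------------------------------------------

read_table_file <- function(path, dialect) {
  if (dialect == "csv") {
    utils::read.csv(path, colClasses = "character", fileEncoding = "UTF-8",
                    check.names = TRUE)
  } else {
    lines <- readLines(path, encoding = "UTF-8")
    lines <- lines[nzchar(trimws(lines))]
    if (length(lines) == 0) return(data.frame())
    rows <- lapply(lines, function(l) {
      r <- jsonlite::fromJSON(l, simplifyVector = TRUE)
      r[vapply(r, is.null, logical(1))] <- NA_character_
      as.data.frame(lapply(r, as.character), stringsAsFactors = FALSE)
    })
    dplyr::bind_rows(rows)
  }
}

# validate raw character rows for one table; returns list(good = typed tibble,
# rejects = tibble(table, row, reason, record))
prepare_rows <- function(raw, which, dialect) {
  need <- cohort_schemas()[[which]]
  rejects <- tibble::tibble(table = character(), row = integer(),
                            reason = character(), record = character())
  if (nrow(raw) == 0) {
    # header-only file: columns must still be present for CSV
    if (dialect == "csv") {
      miss <- setdiff(need, names(raw))
      if (length(miss)) {
        abort_abx(paste0(which, " file missing column(s): ",
                         paste(miss, collapse = ", ")), "abx_validation_error")
      }
    }
    return(list(good = empty_table(which), rejects = rejects))
  }
  miss <- setdiff(need, names(raw))
  if (length(miss)) {
    abort_abx(paste0(which, " file missing column(s): ",
                     paste(miss, collapse = ", ")), "abx_validation_error")
  }
  raw[need][is.na(raw[need])] <- ""
  keep <- rep(TRUE, nrow(raw))
  reason <- rep(NA_character_, nrow(raw))
  mark <- function(bad, why) {
    fresh <- bad & is.na(reason)
    reason[fresh] <<- why
    keep <<- keep & !bad
  }

  out <- NULL
  if (which == "procedures") {
    p <- parse_iso_dt(raw$procedure_datetime)
    mark(!p$ok | raw$procedure_datetime == "", "unparseable procedure_datetime")
    mark(raw$procedure_id == "", "missing procedure_id")
    out <- tibble::tibble(
      procedure_id = raw$procedure_id, patient_id = raw$patient_id,
      facility_id = raw$facility_id, procedure_datetime = p$dt,
      procedure_has_time = p$has_time, procedure_type = raw$procedure_type)
  } else if (which == "notes") {
    d <- parse_iso_dt(raw$signed_date)
    mark(!d$ok | raw$signed_date == "", "unparseable signed_date")
    searchable <- parse_flag(raw$is_searchable)
    mark(is.na(searchable), "unparseable is_searchable")
    out <- tibble::tibble(
      note_id = raw$note_id, patient_id = raw$patient_id,
      signed_date = as_utc_date(d$dt), text = raw$text,
      is_searchable = searchable)
  } else if (which == "orders") {
    o <- parse_iso_dt(raw$order_datetime)
    s <- parse_iso_dt(raw$stop_datetime)
    mark(!o$ok | raw$order_datetime == "", "unparseable order_datetime")
    mark(!s$ok, "unparseable stop_datetime")
    mark(!is.na(s$dt) & !is.na(o$dt) & s$dt < o$dt,
         "stop_datetime before order_datetime")
    out <- tibble::tibble(
      order_id = raw$order_id, patient_id = raw$patient_id,
      drug_name = raw$drug_name,
      route = ifelse(raw$route == "", NA_character_, raw$route),
      order_datetime = o$dt, stop_datetime = s$dt)
  } else if (which == "administrations") {
    a <- parse_iso_dt(raw$admin_datetime)
    mark(!a$ok | raw$admin_datetime == "", "unparseable admin_datetime")
    out <- tibble::tibble(
      admin_id = raw$admin_id, patient_id = raw$patient_id,
      drug_name = raw$drug_name, admin_datetime = a$dt)
  } else if (which == "labels") {
    given <- parse_flag(raw$prophylaxis_given)
    mark(is.na(given), "unparseable prophylaxis_given")
    out <- tibble::tibble(
      procedure_id = raw$procedure_id, prophylaxis_given = given,
      review_source = raw$review_source)
  }
  bad <- which(!keep)
  if (length(bad)) {
    rejects <- tibble::tibble(
      table = which,
      row = bad,
      reason = reason[bad],
      record = vapply(bad, function(i) {
        paste(paste0(need, "=", unlist(raw[i, need])), collapse = "|")
      }, character(1)))
  }
  list(good = out[keep, , drop = FALSE], rejects = rejects)
}

#' Read an EMR cohort from per-table files
#'
#' Expects files `procedures`, `notes`, `orders`, `administrations` and
#' optionally `labels` (extension `.csv` or `.jsonl`) in `dir`, or explicit
#' paths via `paths`. Structural problems (a missing column) abort; malformed
#' rows (unparseable datetimes or flags, stop before start) are collected into
#' a rejects report — available as `attr(cohort, "rejects")` — rather than
#' silently dropped.
#'
#' @param dir Directory containing the table files.
#' @param dialect `"csv"` (UTF-8, header row, ISO-8601 datetimes, empty string
#'   = absent) or `"jsonl"` (one record per line, same field names).
#' @param paths Optional named list/character vector overriding individual
#'   table paths (`procedures`, `notes`, `orders`, `administrations`,
#'   `labels`).
#' @return A validated `abx_cohort` with a `rejects` attribute.
#' @export
read_cohort <- function(dir = NULL, dialect = c("csv", "jsonl"), paths = NULL) {
  dialect <- match.arg(dialect)
  ext <- if (dialect == "csv") ".csv" else ".jsonl"
  tables <- c("procedures", "notes", "orders", "administrations", "labels")
  got <- list()
  rejects <- list()
  for (tb in tables) {
    path <- paths[[tb]] %||% if (!is.null(dir)) file.path(dir, paste0(tb, ext))
    if (is.null(path) || !file.exists(path)) {
      if (tb == "labels") { got[[tb]] <- NULL; next }
      abort_abx(paste0("cohort table file not found: ",
                       path %||% paste0(tb, ext)), "abx_io_error")
    }
    raw <- read_table_file(path, dialect)
    pr <- prepare_rows(raw, tb, dialect)
    got[[tb]] <- pr$good
    rejects[[tb]] <- pr$rejects
  }
  cohort <- emr_cohort(procedures = got$procedures, notes = got$notes,
                       orders = got$orders,
                       administrations = got$administrations,
                       labels = got$labels)
  attr(cohort, "rejects") <- dplyr::bind_rows(rejects)
  scen_path <- if (!is.null(dir)) file.path(dir, paste0("scenarios", ext))
  if (!is.null(scen_path) && file.exists(scen_path)) {
    sc <- read_table_file(scen_path, dialect)
    sc$gold_label <- parse_flag(sc$gold_label)
    attr(cohort, "scenarios") <- tibble::as_tibble(sc)
  }
  cohort
}

#' Write an EMR cohort to per-table files
#'
#' Inverse of [read_cohort()]; the round trip is lossless, including absent
#' optional fields (written as empty strings in CSV). A scenario-annotation
#' sidecar (`scenarios` attribute, as attached by [generate_cohort()]) is
#' written alongside when present.
#'
#' @param cohort An `abx_cohort`.
#' @param dir Output directory (created if needed).
#' @param dialect `"csv"` or `"jsonl"`.
#' @return `dir`, invisibly.
#' @export
write_cohort <- function(cohort, dir, dialect = c("csv", "jsonl")) {
  dialect <- match.arg(dialect)
  ext <- if (dialect == "csv") ".csv" else ".jsonl"
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)

  serialize_table <- function(tb, which) {
    df <- as.data.frame(tb)
    if (which == "procedures") {
      df$procedure_datetime <- format_iso_dt(df$procedure_datetime,
                                             df$procedure_has_time)
      df$procedure_has_time <- NULL
    } else if (which == "notes") {
      df$signed_date <- format(df$signed_date, "%Y-%m-%d")
    } else if (which == "orders") {
      df$order_datetime <- format_iso_dt(df$order_datetime)
      df$stop_datetime <- format_iso_dt(df$stop_datetime)
      df$route[is.na(df$route)] <- ""
    } else if (which == "administrations") {
      df$admin_datetime <- format_iso_dt(df$admin_datetime)
    }
    df$orphan <- NULL
    df
  }
  write_one <- function(df, path) {
    if (dialect == "csv") {
      utils::write.csv(df, path, row.names = FALSE, fileEncoding = "UTF-8")
    } else {
      con <- file(path, open = "w", encoding = "UTF-8")
      on.exit(close(con))
      if (nrow(df) > 0) {
        for (i in seq_len(nrow(df))) {
          writeLines(as.character(
            jsonlite::toJSON(as.list(df[i, ]), auto_unbox = TRUE, na = "string")),
            con)
        }
      }
    }
  }
  for (tb in c("procedures", "notes", "orders", "administrations")) {
    write_one(serialize_table(cohort[[tb]], tb), file.path(dir, paste0(tb, ext)))
  }
  if (!is.null(cohort$labels)) {
    write_one(as.data.frame(cohort$labels), file.path(dir, paste0("labels", ext)))
  }
  sc <- attr(cohort, "scenarios")
  if (!is.null(sc)) {
    write_one(as.data.frame(sc), file.path(dir, paste0("scenarios", ext)))
  }
  invisible(dir)
}

#' Deduplicate procedures and drop out-of-scope procedure types
#'
#' Procedures identical on (`patient_id`, `procedure_datetime`,
#' `procedure_type`) collapse to one record (the first in `procedure_id`
#' order); procedures whose `procedure_type` is not in `target_types` — e.g. a
#' cardiac catheterization miscoded into a cardiac device cohort — are
#' removed. Idempotent. Every removal is listed, with its reason, in the
#' `removal_report` attribute of the returned cohort.
#'
#' @param cohort An `abx_cohort`.
#' @param target_types Character vector of in-scope `procedure_type` values.
#' @return The filtered `abx_cohort`, with attribute `removal_report`:
#'   a tibble (`procedure_id`, `reason`).
#' @export
dedupe_procedures <- function(cohort, target_types = "cardiac device") {
  p <- cohort$procedures
  removals <- tibble::tibble(procedure_id = character(), reason = character())
  if (nrow(p) > 0) {
    p <- p[order(p$procedure_id), , drop = FALSE]
    key <- paste(p$patient_id, format_iso_dt(p$procedure_datetime,
                                             p$procedure_has_time),
                 p$procedure_type, sep = "\r")
    dup <- duplicated(key)
    if (any(dup)) {
      first_of <- p$procedure_id[match(key[dup], key)]
      removals <- dplyr::bind_rows(removals, tibble::tibble(
        procedure_id = p$procedure_id[dup],
        reason = paste0("duplicate of ", first_of)))
      p <- p[!dup, , drop = FALSE]
    }
    off_type <- !(p$procedure_type %in% target_types)
    if (any(off_type)) {
      removals <- dplyr::bind_rows(removals, tibble::tibble(
        procedure_id = p$procedure_id[off_type],
        reason = paste0("procedure_type '", p$procedure_type[off_type],
                        "' not in target set")))
      p <- p[!off_type, , drop = FALSE]
    }
  }
  labels <- cohort$labels
  if (!is.null(labels)) {
    labels <- labels[labels$procedure_id %in% p$procedure_id, , drop = FALSE]
  }
  out <- emr_cohort(procedures = p, notes = cohort$notes,
                    orders = cohort$orders,
                    administrations = cohort$administrations, labels = labels)
  attr(out, "rejects") <- attr(cohort, "rejects")
  sc <- attr(cohort, "scenarios")
  if (!is.null(sc)) {
    attr(out, "scenarios") <- sc[sc$procedure_id %in% p$procedure_id, ,
                                 drop = FALSE]
  }
  attr(out, "removal_report") <- removals
  out
}
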