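# shared builders for tiny hand-constructed fixtures

utc <- function(x) as.POSIXct(x, tz = "UTC")

p_row <- function(id = "PR1", pid = "P1", fac = "F01",
                  dt = "2016-03-10 09:00", type = "cardiac device",
                  has_time = TRUE) {
  tibble::tibble(procedure_id = id, patient_id = pid, facility_id = fac,
                 procedure_datetime = utc(dt), procedure_has_time = has_time,
                 procedure_type = type)
}

note_row <- function(id = "N1", pid = "P1", date = "2016-03-10",
                     text = "", searchable = TRUE) {
  tibble::tibble(note_id = id, patient_id = pid,
                 signed_date = as.Date(date), text = text,
                 is_searchable = searchable)
}

order_row <- function(id = "O1", pid = "P1", drug = "cefazolin",
                      start = "2016-03-10 07:00", stop = NA) {
  tibble::tibble(order_id = id, patient_id = pid, drug_name = drug,
                 route = "IV", order_datetime = utc(start),
                 stop_datetime = if (is.na(stop[1]))
                   as.POSIXct(NA, tz = "UTC") else utc(stop))
}

admin_row <- function(id = "A1", pid = "P1", drug = "cefazolin",
                      when = "2016-03-10 07:30") {
  tibble::tibble(admin_id = id, patient_id = pid, drug_name = drug,
                 admin_datetime = utc(when))
}

label_row <- function(id = "PR1", given = TRUE, source = "synthetic") {
  tibble::tibble(procedure_id = id, prophylaxis_given = given,
                 review_source = source)
}

tiny_lexicon <- function() {
  lexicon(tibble::tribble(
    ~alias, ~canonical_name, ~oral_only, ~rarely_prophylactic, ~text_search_excluded,
    "cefazolin", "cefazolin", FALSE, FALSE, FALSE,
    "ancef", "cefazolin", FALSE, FALSE, FALSE,
    "vancomycin", "vancomycin", FALSE, FALSE, FALSE,
    "keflex", "cephalexin", TRUE, FALSE, FALSE,
    "cephalexin", "cephalexin", TRUE, FALSE, FALSE,
    "azithromycin", "azithromycin", FALSE, TRUE, FALSE,
    "penicillin", "penicillin", FALSE, TRUE, TRUE
  ), version = "tiny")
}

# single-case cohort with a given note/order/admin set
one_case_cohort <- function(procedure = p_row(), notes = NULL, orders = NULL,
                            admins = NULL, given = TRUE) {
  emr_cohort(
    procedures = procedure,
    notes = if (is.null(notes)) abxflag:::empty_table("notes") else notes,
    orders = if (is.null(orders)) abxflag:::empty_table("orders") else orders,
    administrations = if (is.null(admins))
      abxflag:::empty_table("administrations") else admins,
    labels = label_row(procedure$procedure_id, given))
}

# brute-force whole-word case-insensitive scan: independent oracle for
# match_text (per-position alias comparison, longest alias first)
scan_oracle <- function(text, aliases) {
  lt <- tolower(text)
  aliases <- aliases[order(-nchar(aliases))]
  hits <- list()
  i <- 1L
  nch <- nchar(lt)
  is_word <- function(ch) grepl("^[[:alnum:]]$", ch)
  while (i <= nch) {
    matched <- FALSE
    for (a in aliases) {
      j <- i + nchar(a) - 1L
      if (j > nch) next
      if (substr(lt, i, j) == a &&
          (i == 1L || !is_word(substr(lt, i - 1L, i - 1L))) &&
          (j == nch || !is_word(substr(lt, j + 1L, j + 1L)))) {
        hits[[length(hits) + 1L]] <- list(start = i, alias = a)
        i <- j + 1L
        matched <- TRUE
        break
      }
    }
    if (!matched) i <- i + 1L
  }
  hits
}
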