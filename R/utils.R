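# internal helpers shared across modules

#' Normalize a drug-name surface string
#'
#' Lower-cases, trims leading/trailing whitespace and collapses internal runs
#' of whitespace to a single space. This is the canonical form used for every
#' alias lookup: lexicon aliases, order `drug_name` fields and matched note
#' slices are all compared after normalization.
#'
#' @param x Character vector.
#' @return Character vector of the same length.
#' @export
#' @examples
#' normalize_term("  CeFAZolin   1g ")
normalize_term <- function(x) {
  x <- tolower(trimws(x))
  gsub("[[:space:]]+", " ", x)
}

# escape regex metacharacters in an alias before building the matcher pattern
regex_escape <- function(x) {
  gsub("([][{}()+*^$|\\\\?.])", "\\\\\\1", x)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

abort_abx <- function(msg, class) {
  stop(structure(
    class = c(class, "abx_error", "error", "condition"),
    list(message = msg, call = NULL)
  ))
}

# ---- datetime handling -------------------------------------------------------
# All timestamps are naive local times stored as POSIXct in UTC (single-
# institution assumption; no timezone arithmetic). Accepted input forms are
# ISO-8601 "YYYY-MM-DD" (date only) and "YYYY-MM-DDTHH:MM[:SS]" (space also
# tolerated in place of "T").

# returns list(dt = POSIXct, has_time = logical, ok = logical)
parse_iso_dt <- function(x) {
  x <- trimws(as.character(x))
  n <- length(x)
  dt <- as.POSIXct(rep(NA_real_, n), origin = "1970-01-01", tz = "UTC")
  has_time <- rep(NA, n)
  ok <- rep(FALSE, n)
  blank <- is.na(x) | x == ""
  ok[blank] <- TRUE          # absent optional value: ok, dt stays NA
  date_only <- !blank & grepl("^\\d{4}-\\d{2}-\\d{2}$", x)
  with_time <- !blank & grepl("^\\d{4}-\\d{2}-\\d{2}[T ]\\d{2}:\\d{2}(:\\d{2})?$", x)
  if (any(date_only)) {
    d <- as.Date(x[date_only], format = "%Y-%m-%d")
    good <- !is.na(d)
    dt[date_only][good] <- as.POSIXct(d[good], tz = "UTC")
    has_time[date_only][good] <- FALSE
    ok[date_only][good] <- TRUE
  }
  if (any(with_time)) {
    xt <- sub("T", " ", x[with_time], fixed = TRUE)
    xt <- ifelse(grepl(":\\d{2}:\\d{2}$", xt), xt, paste0(xt, ":00"))
    p <- as.POSIXct(xt, format = "%Y-%m-%d %H:%M:%S", tz = "UTC")
    good <- !is.na(p)
    dt[with_time][good] <- p[good]
    has_time[with_time][good] <- TRUE
    ok[with_time][good] <- TRUE
  }
  list(dt = dt, has_time = has_time, ok = ok)
}

format_iso_dt <- function(dt, has_time = NULL) {
  out <- character(length(dt))
  out[is.na(dt)] <- ""
  idx <- !is.na(dt)
  if (is.null(has_time)) has_time <- rep(TRUE, length(dt))
  ht <- has_time
  ht[is.na(ht)] <- TRUE
  out[idx & ht] <- format(dt[idx & ht], "%Y-%m-%dT%H:%M", tz = "UTC")
  out[idx & !ht] <- format(dt[idx & !ht], "%Y-%m-%d", tz = "UTC")
  out
}

as_utc_date <- function(dt) as.Date(dt, tz = "UTC")
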