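#' Antimicrobial lexicon
#'
#' A lexicon maps surface strings (generic names, brand names, deliberate
#' misspelling variants) to canonical antimicrobial agents, and carries the
#' per-agent attributes that the detection-algorithm variants filter on:
#'
#' * `oral_only` — the agent is available only in oral formulation, so a
#'   mention is unlikely to reflect intravenous pre-incisional prophylaxis;
#' * `rarely_prophylactic` — the agent is rarely used for surgical/procedural
#'   prophylaxis (e.g. agents typically prescribed to treat infections);
#' * `text_search_excluded` — the agent is dropped from clinical-note text
#'   searches only (the classic case is penicillin, which appears in notes
#'   overwhelmingly as an allergy mention), but still matches structured
#'   order/administration records.
#'
#' @param entries A data frame with one row per alias and columns
#'   `alias`, `canonical_name`, `oral_only`, `rarely_prophylactic`,
#'   `text_search_excluded`. Aliases and canonical names are normalized with
#'   [normalize_term()]; the canonical name is added to its own alias set if
#'   absent. Per-agent attribute flags must be consistent across the rows of
#'   one agent.
#' @param version Free-text label identifying the lexicon revision.
#' @return An object of class `abx_lexicon`: a tibble of normalized alias
#'   rows with a `version` attribute.
#' @seealso [read_lexicon()], [default_lexicon()], [build_matcher()]
#' @export
lexicon <- function(entries, version = "unversioned") {
  entries <- tibble::as_tibble(entries)
  req <- c("alias", "canonical_name", "oral_only", "rarely_prophylactic",
           "text_search_excluded")
  missing_cols <- setdiff(req, names(entries))
  if (length(missing_cols) > 0) {
    abort_abx(paste0("lexicon entries missing column(s): ",
                     paste(missing_cols, collapse = ", ")),
              "abx_validation_error")
  }
  if (nrow(entries) == 0) {
    abort_abx("lexicon has no entries", "abx_validation_error")
  }
  entries$alias <- normalize_term(entries$alias)
  entries$canonical_name <- normalize_term(entries$canonical_name)
  for (col in c("oral_only", "rarely_prophylactic", "text_search_excluded")) {
    entries[[col]] <- as.logical(entries[[col]])
    if (anyNA(entries[[col]])) {
      abort_abx(paste0("lexicon column '", col, "' has missing values"),
                "abx_validation_error")
    }
  }
  if (any(entries$canonical_name == "" | entries$alias == "")) {
    abort_abx("empty alias or canonical_name in lexicon", "abx_validation_error")
  }

  # attribute flags must agree within an agent
  attr_chk <- stats::aggregate(
    entries[c("oral_only", "rarely_prophylactic", "text_search_excluded")],
    by = list(canonical_name = entries$canonical_name),
    FUN = function(v) length(unique(v))
  )
  bad <- attr_chk$canonical_name[rowSums(attr_chk[-1] > 1) > 0]
  if (length(bad) > 0) {
    abort_abx(paste0("inconsistent agent attributes for: ",
                     paste(bad, collapse = ", ")),
              "abx_validation_error")
  }

  # ensure canonical_name is a member of its own alias set
  agents <- unique(entries[c("canonical_name", "oral_only",
                             "rarely_prophylactic", "text_search_excluded")])
  have_self <- mapply(function(cn) any(entries$alias == cn &
                                         entries$canonical_name == cn),
                      agents$canonical_name)
  if (any(!have_self)) {
    self_rows <- agents[!have_self, ]
    self_rows$alias <- self_rows$canonical_name
    entries <- dplyr::bind_rows(entries, self_rows)
  }
  entries <- dplyr::distinct(entries)
  entries <- dplyr::arrange(entries, .data$canonical_name, .data$alias)

  # no alias may map to two canonical names
  dup <- entries[duplicated(entries$alias) | duplicated(entries$alias, fromLast = TRUE), ]
  if (nrow(dup) > 0) {
    coll <- dplyr::summarise(
      dplyr::group_by(dup, .data$alias),
      canonicals = paste(unique(.data$canonical_name), collapse = " / ")
    )
    abort_abx(paste0("alias maps to multiple agents: ",
                     paste(paste0("'", coll$alias, "' -> ", coll$canonicals),
                           collapse = "; ")),
              "abx_validation_error")
  }

  structure(entries, class = c("abx_lexicon", class(entries)),
            version = version)
}

#' @export
print.abx_lexicon <- function(x, ...) {
  cat("<abx_lexicon> version:", attr(x, "version"), "\n")
  cat("  ", length(unique(x$canonical_name)), "agents,", nrow(x), "aliases\n")
  invisible(x)
}

#' Read an antimicrobial lexicon file
#'
#' Two on-disk layouts are supported. `format = "csv"`: one row per alias with
#' columns `alias, canonical_name, oral_only, rarely_prophylactic,
#' text_search_excluded`. `format = "json"`: an array of agent objects
#' `{canonical_name, aliases: [...], oral_only, rarely_prophylactic,
#' text_search_excluded}`.
#'
#' @param path Path to the lexicon file (UTF-8).
#' @param format `"csv"` or `"json"`.
#' @param version Optional version label; defaults to the file name.
#' @return An `abx_lexicon` (see [lexicon()]). An alias listed under two
#'   different agents is rejected.
#' @export
read_lexicon <- function(path, format = c("csv", "json"), version = NULL) {
  format <- match.arg(format)
  if (!file.exists(path)) {
    abort_abx(paste0("lexicon file not found: ", path), "abx_io_error")
  }
  if (format == "csv") {
    raw <- utils::read.csv(path, colClasses = "character",
                           fileEncoding = "UTF-8")
    for (col in c("oral_only", "rarely_prophylactic", "text_search_excluded")) {
      if (col %in% names(raw)) raw[[col]] <- parse_flag(raw[[col]])
    }
    entries <- raw
  } else {
    objs <- jsonlite::fromJSON(path, simplifyDataFrame = FALSE)
    entries <- dplyr::bind_rows(lapply(objs, function(o) {
      tibble::tibble(
        alias = unique(c(o$canonical_name, unlist(o$aliases))),
        canonical_name = o$canonical_name,
        oral_only = isTRUE(o$oral_only),
        rarely_prophylactic = isTRUE(o$rarely_prophylactic),
        text_search_excluded = isTRUE(o$text_search_excluded)
      )
    }))
  }
  lexicon(entries, version = version %||% basename(path))
}

parse_flag <- function(x) {
  v <- tolower(trimws(x))
  out <- rep(NA, length(v))
  out[v %in% c("true", "t", "1", "yes")] <- TRUE
  out[v %in% c("false", "f", "0", "no", "")] <- FALSE
  out
}

#' Write a lexicon back to disk
#'
#' @param lex An `abx_lexicon`.
#' @param path Output file path.
#' @param format `"csv"` or `"json"` (same layouts as [read_lexicon()]).
#' @return `path`, invisibly.
#' @export
write_lexicon <- function(lex, path, format = c("csv", "json")) {
  format <- match.arg(format)
  if (format == "csv") {
    utils::write.csv(as.data.frame(lex), path, row.names = FALSE,
                     fileEncoding = "UTF-8")
  } else {
    agents <- split(lex$alias, lex$canonical_name)
    attrs <- unique(as.data.frame(lex)[c("canonical_name", "oral_only",
                                         "rarely_prophylactic",
                                         "text_search_excluded")])
    objs <- lapply(attrs$canonical_name, function(cn) {
      a <- attrs[attrs$canonical_name == cn, ]
      list(canonical_name = cn,
           aliases = unname(setdiff(agents[[cn]], cn)),
           oral_only = a$oral_only,
           rarely_prophylactic = a$rarely_prophylactic,
           text_search_excluded = a$text_search_excluded)
    })
    jsonlite::write_json(objs, path, auto_unbox = TRUE, pretty = TRUE)
  }
  invisible(path)
}

#' The default antimicrobial lexicon shipped with the package
#'
#' A guideline-derived list of agents used for pre-incisional prophylaxis
#' before cardiac device procedures (first-line cephalosporins, vancomycin and
#' clindamycin for beta-lactam-allergic patients), plus brand names and common
#' misspellings; cephalexin is flagged `oral_only`, and penicillin — rarely
#' used for prophylaxis but ubiquitously documented as an allergy — is flagged
#' `rarely_prophylactic` and `text_search_excluded`. The list is fully
#' user-overridable: pass any file through [read_lexicon()] instead.
#'
#' @return An `abx_lexicon`.
#' @export
default_lexicon <- function() {
  path <- system.file("extdata", "antimicrobial_lexicon.csv",
                      package = "abxflag", mustWork = TRUE)
  read_lexicon(path, format = "csv", version = "abxflag-default-1")
}

# agents surviving a variant's structured-data filters (orders/administrations)
agent_filter <- function(lex, variant, for_text = FALSE) {
  keep <- rep(TRUE, nrow(lex))
  if (for_text) keep <- keep & !lex$text_search_excluded
  if (isTRUE(variant$exclude_oral_only)) keep <- keep & !lex$oral_only
  if (isTRUE(variant$restrict_common_prophylaxis)) {
    keep <- keep & !lex$rarely_prophylactic
  }
  lex_df <- as.data.frame(lex)[keep, c("alias", "canonical_name")]
  tibble::as_tibble(lex_df)
}

#' Compile a lexicon into a clinical-note text matcher
#'
#' Applies the active variant's lexicon filters and compiles the surviving
#' aliases into a single case-insensitive, whole-word regular expression.
#' Agents flagged `text_search_excluded` are always dropped for note matching;
#' `oral_only` agents are dropped when `variant$exclude_oral_only`;
#' `rarely_prophylactic` agents are dropped when
#' `variant$restrict_common_prophylaxis`. When
#' `variant$include_prophylaxis_term`, the bare word "prophylaxis" is added as
#' a nonspecific pseudo-agent.
#'
#' @param lex An `abx_lexicon`.
#' @param variant An [algorithm_variant()].
#' @return An object of class `abx_matcher`.
#' @export
build_matcher <- function(lex, variant = algorithm_variant()) {
  tab <- agent_filter(lex, variant, for_text = TRUE)
  if (isTRUE(variant$include_prophylaxis_term)) {
    tab <- dplyr::bind_rows(
      tab, tibble::tibble(alias = "prophylaxis", canonical_name = "prophylaxis"))
  }
  if (nrow(tab) == 0) {
    abort_abx("variant filters removed every lexicon entry: empty matcher",
              "abx_validation_error")
  }
  # longest alias first so alternation prefers the longest match at an offset
  tab <- tab[order(-nchar(tab$alias), tab$alias), ]
  pattern <- paste0("(?<![[:alnum:]])(?:",
                    paste(regex_escape(tab$alias), collapse = "|"),
                    ")(?![[:alnum:]])")
  structure(list(aliases = tab, pattern = pattern),
            class = "abx_matcher")
}

#' @export
print.abx_matcher <- function(x, ...) {
  cat("<abx_matcher>", nrow(x$aliases), "aliases,",
      length(unique(x$aliases$canonical_name)), "agents\n")
  invisible(x)
}

#' Find antimicrobial-name mentions in free text
#'
#' Scans `text` for all non-overlapping, case-insensitive, whole-word
#' (alphanumeric-boundary) occurrences of any alias in the matcher. When two
#' aliases could match at the same offset the longest wins. Matches are
#' returned ordered by `start`. No negation or allergy handling is done: an
#' allergy mention of a retained agent matches (the only allergy mitigation is
#' excluding such agents from the text lexicon).
#'
#' @param text A single character string (may be empty or `NA`, yielding no
#'   matches).
#' @param matcher An `abx_matcher` from [build_matcher()].
#' @param source_id Optional identifier of the record the text came from,
#'   carried into the result for the evidence trail.
#' @return A tibble with one row per match: `canonical_name`, `surface_form`
#'   (the text slice exactly as matched), `start` (1-based character offset)
#'   and `source_id`.
#' @export
match_text <- function(text, matcher, source_id = NA_character_) {
  empty <- tibble::tibble(canonical_name = character(),
                          surface_form = character(),
                          start = integer(),
                          source_id = character())
  if (is.null(text) || length(text) == 0 || is.na(text) || !nzchar(text)) {
    return(empty)
  }
  m <- gregexpr(matcher$pattern, text, perl = TRUE, ignore.case = TRUE)[[1]]
  if (m[1] == -1) return(empty)
  starts <- as.integer(m)
  lens <- attr(m, "match.length")
  surface <- substring(text, starts, starts + lens - 1L)
  key <- normalize_term(surface)
  canon <- matcher$aliases$canonical_name[match(key, matcher$aliases$alias)]
  tibble::tibble(canonical_name = canon,
                 surface_form = surface,
                 start = starts,
                 source_id = rep(as.character(source_id), length(starts)))
}
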