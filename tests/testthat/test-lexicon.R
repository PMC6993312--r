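test_that("lexicon files round-trip and aliases resolve to one agent", {
  lex <- tiny_lexicon()
  expect_s3_class(lex, "abx_lexicon")
  # one-entry file: canonical + 2 variants -> 3 aliases, all to cefazolin
  csv <- tempfile(fileext = ".csv")
  writeLines(c("alias,canonical_name,oral_only,rarely_prophylactic,text_search_excluded",
               "cefazolin,cefazolin,false,false,false",
               "ancef,cefazolin,false,false,false",
               "cefazolen,cefazolin,false,false,false"), csv)
  one <- read_lexicon(csv)
  expect_equal(length(unique(one$canonical_name)), 1L)
  expect_setequal(one$alias, c("cefazolin", "ancef", "cefazolen"))

  for (fmt in c("csv", "json")) {
    path <- tempfile(fileext = paste0(".", fmt))
    write_lexicon(lex, path, format = fmt)
    back <- read_lexicon(path, format = fmt)
    expect_equal(
      back[order(back$alias), c("alias", "canonical_name", "oral_only",
                                "rarely_prophylactic", "text_search_excluded")],
      lex[order(lex$alias), c("alias", "canonical_name", "oral_only",
                              "rarely_prophylactic", "text_search_excluded")],
      ignore_attr = TRUE)
  }
})

test_that("invalid lexicons are rejected with informative errors", {
  # same alias under two agents
  expect_error(
    lexicon(tibble::tribble(
      ~alias, ~canonical_name, ~oral_only, ~rarely_prophylactic, ~text_search_excluded,
      "ancef", "cefazolin", FALSE, FALSE, FALSE,
      "ancef", "vancomycin", FALSE, FALSE, FALSE)),
    class = "abx_validation_error", regexp = "cefazolin.*vancomycin")
  expect_error(lexicon(data.frame()), class = "abx_validation_error")
  expect_error(read_lexicon(tempfile()), class = "abx_io_error")
})

test_that("shipped default lexicon resolves every alias exhaustively", {
  lex <- default_lexicon()
  expect_gt(nrow(lex), 0)
  for (i in seq_len(nrow(lex))) {
    hits <- lex$canonical_name[lex$alias == lex$alias[i]]
    expect_length(unique(hits), 1L)
  }
  # each canonical name is a member of its own alias set
  for (cn in unique(lex$canonical_name)) {
    expect_true(cn %in% lex$alias[lex$canonical_name == cn])
  }
})

test_that("matcher alias sets equal a brute-force filter comprehension", {
  lex <- tiny_lexicon()
  df <- as.data.frame(lex)
  cases <- list(
    algorithm_variant(),
    algorithm_variant(exclude_oral_only = TRUE),
    algorithm_variant(restrict_common_prophylaxis = TRUE),
    algorithm_variant(exclude_oral_only = TRUE,
                      restrict_common_prophylaxis = TRUE),
    algorithm_variant(include_prophylaxis_term = TRUE)
  )
  for (v in cases) {
    keep <- !df$text_search_excluded
    if (v$exclude_oral_only) keep <- keep & !df$oral_only
    if (v$restrict_common_prophylaxis) keep <- keep & !df$rarely_prophylactic
    want <- df$alias[keep]
    if (v$include_prophylaxis_term) want <- c(want, "prophylaxis")
    got <- build_matcher(lex, v)$aliases$alias
    expect_setequal(got, want)
  }
  # filters that exhaust the lexicon produce an empty-matcher error
  oral_only_lex <- lexicon(tibble::tibble(
    alias = "keflex", canonical_name = "cephalexin", oral_only = TRUE,
    rarely_prophylactic = FALSE, text_search_excluded = FALSE))
  expect_error(build_matcher(oral_only_lex,
                             algorithm_variant(exclude_oral_only = TRUE)),
               class = "abx_validation_error", regexp = "empty matcher")
})

test_that("match_text agrees with an independent substring-scan oracle", {
  m <- build_matcher(default_lexicon(), algorithm_variant())
  texts <- c(
    "Cefazolin 1 g IV administered prior to incision",
    "gave ANCEF then more Ancef later; vancomicin held",
    "acefazolin cefazolinx embedded words must not match",
    "penicillin allergy noted",          # excluded from text searches
    "Rocephin/ceftin, punctuation-bound keflex.",
    "")
  for (tx in texts) {
    got <- match_text(tx, m)
    want <- scan_oracle(tx, m$aliases$alias)
    expect_equal(nrow(got), length(want), info = tx)
    if (length(want)) {
      expect_equal(got$start, vapply(want, `[[`, integer(1), "start"))
      expect_equal(normalize_term(got$surface_form),
                   vapply(want, `[[`, character(1), "alias"))
    }
  }
  first <- match_text(texts[1], m)
  expect_equal(first$canonical_name, "cefazolin")
  expect_equal(first$start, 1L)
  expect_equal(nrow(match_text("penicillin allergy noted", m)), 0L)
})

test_that("longest alias wins at a shared offset", {
  lex <- lexicon(tibble::tribble(
    ~alias, ~canonical_name, ~oral_only, ~rarely_prophylactic, ~text_search_excluded,
    "cefazolin", "cefazolin", FALSE, FALSE, FALSE,
    "cefazolin sodium", "cefazolin", FALSE, FALSE, FALSE))
  m <- build_matcher(lex, algorithm_variant())
  got <- match_text("cefazolin sodium 2 g", m)
  expect_equal(got$surface_form, "cefazolin sodium")
})

test_that("matching is deterministic, idempotent, and self-revalidating; shrinking the lexicon never adds matches", {
  set.seed(71)
  full <- default_lexicon()
  m_full <- build_matcher(full, algorithm_variant())
  words <- c(full$alias, "patient", "incision", "given", "iv", "prior",
             "allergy", "noted.", "dose;")
  for (rep in 1:20) {
    tx <- paste(sample(words, 12, replace = TRUE), collapse = " ")
    a <- match_text(tx, m_full)
    expect_identical(a, match_text(tx, m_full))  # deterministic
    # every reported match re-validates against the text slice
    if (nrow(a)) {
      slice <- substring(tx, a$start, a$start + nchar(a$surface_form) - 1L)
      expect_identical(slice, a$surface_form)
      expect_true(all(normalize_term(slice) %in% m_full$aliases$alias))
    }
    # random agent-subset deletion: anti-monotonicity
    keep_agents <- sample(unique(full$canonical_name),
                          size = sample(1:6, 1))
    sub <- lexicon(as.data.frame(full)[full$canonical_name %in% keep_agents, ])
    m_sub <- try(build_matcher(sub, algorithm_variant()), silent = TRUE)
    if (!inherits(m_sub, "try-error")) {
      b <- match_text(tx, m_sub)
      expect_lte(nrow(b), nrow(a))
      expect_true(all(b$canonical_name %in% a$canonical_name))
    }
  }
})
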