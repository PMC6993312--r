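lex <- tiny_lexicon()

test_that("note window honors the day-of-procedure bound and scanned notes are blind", {
  proc <- p_row(dt = "2016-03-10 09:00")
  m <- build_matcher(lex, algorithm_variant())
  day_of <- note_row(date = "2016-03-10", text = "cefazolin 1 g IV given")
  expect_true(flag_text(proc, day_of, m, algorithm_variant())$hit)
  expect_false(flag_text(proc, day_of, m,
                         algorithm_variant(exclude_day_of_procedure_notes = TRUE))$hit)
  # window edges: 7 days before in, 8 days before out, day after out
  expect_true(flag_text(proc, note_row(date = "2016-03-03",
                                       text = "ancef given"), m,
                        algorithm_variant())$hit)
  expect_false(flag_text(proc, note_row(date = "2016-03-02",
                                        text = "ancef given"), m,
                         algorithm_variant())$hit)
  expect_false(flag_text(proc, note_row(date = "2016-03-11",
                                        text = "ancef given"), m,
                         algorithm_variant())$hit)
  # scanned documentation never matches
  scanned <- note_row(date = "2016-03-10", text = "cefazolin 1 g IV given",
                      searchable = FALSE)
  expect_false(flag_text(proc, scanned, m, algorithm_variant())$hit)
})

test_that("order flag applies window, same-day-time, duration and agent filters", {
  proc <- p_row(dt = "2016-03-10 09:00")
  fv <- final_variant()
  # 10 days before -> out of window
  expect_false(flag_orders(proc, order_row(start = "2016-02-29 08:00"),
                           lex, fv)$hit)
  # same day, 2 h after procedure: excluded under final, counted without the rule
  late <- order_row(start = "2016-03-10 11:00")
  expect_false(flag_orders(proc, late, lex, fv)$hit)
  expect_true(flag_orders(proc, late, lex,
                          algorithm_variant(use_orders = TRUE))$hit)
  # 72-hour order fails the <24h cap; passes with the cap absent
  long <- order_row(start = "2016-03-09 08:00", stop = "2016-03-12 08:00")
  expect_false(flag_orders(proc, long, lex, fv)$hit)
  expect_true(flag_orders(proc, long, lex,
                          algorithm_variant(use_orders = TRUE))$hit)
  # absent stop time passes the duration cap, flagged in evidence
  open <- order_row(start = "2016-03-09 08:00", stop = NA)
  r <- flag_orders(proc, open, lex, fv)
  expect_true(r$hit)
  expect_true(r$evidence$stop_missing)
  # brand alias normalizes; oral-only and rarely-prophylactic agents filtered
  expect_true(flag_orders(proc, order_row(drug = " ANCEF ",
                                          start = "2016-03-09 08:00"),
                          lex, fv)$hit)
  expect_false(flag_orders(proc, order_row(drug = "keflex",
                                           start = "2016-03-09 08:00"),
                           lex, fv)$hit)
  expect_false(flag_orders(proc, order_row(drug = "azithromycin",
                                           start = "2016-03-09 08:00"),
                           lex, fv)$hit)
  # penicillin is excluded from text searches only: its order still counts
  expect_true(flag_orders(proc, order_row(drug = "penicillin",
                                          start = "2016-03-09 08:00"),
                          lex, algorithm_variant(use_orders = TRUE))$hit)
})

test_that("same-day orders under a date-only procedure follow the configured policy", {
  proc <- p_row(dt = "2016-03-10", has_time = FALSE)
  fv <- final_variant()
  same_day <- order_row(start = "2016-03-10 14:00")
  expect_true(flag_orders(proc, same_day, lex, fv)$hit)  # default: include
  expect_false(flag_orders(proc, same_day, lex, fv,
                           same_day_policy = "exclude")$hit)
})

test_that("administration flag rejects post-procedure and stale administrations", {
  proc <- p_row(dt = "2016-03-10 09:00")
  va <- algorithm_variant(use_text = FALSE, use_admin = TRUE)
  expect_true(flag_admin(proc, admin_row(when = "2016-03-09 08:00"), lex, va)$hit)
  expect_false(flag_admin(proc, admin_row(when = "2016-03-10 10:00"), lex, va)$hit)
  expect_false(flag_admin(proc, admin_row(when = "2016-03-01 08:00"), lex, va)$hit)
  # exhaustive-scan oracle over a random administration table
  set.seed(5)
  whens <- utc("2016-03-10 09:00") + as.difftime(
    sample(seq(-12 * 24, 3 * 24), 40), units = "hours")
  drugs <- sample(c("cefazolin", "keflex", "ibuprofen", "vancomycin"), 40,
                  replace = TRUE)
  tab <- tibble::tibble(admin_id = sprintf("A%02d", 1:40), patient_id = "P1",
                        drug_name = drugs, admin_datetime = whens)
  got <- flag_admin(proc, tab, lex, final_variant())
  agents <- c("cefazolin", "vancomycin")   # survive final filters
  want <- drugs %in% agents & whens <= utc("2016-03-10 09:00") &
    as.Date(whens, tz = "UTC") >= as.Date("2016-03-03")
  expect_equal(got$hit, any(want))
  expect_setequal(got$evidence$admin_id, tab$admin_id[want])
})

test_that("per-procedure classification composes source flags disjunctively", {
  # order-only documentation still earns the final flag
  co <- one_case_cohort(
    p_row(), notes = note_row(text = "antibiotics given pre-incision"),
    orders = order_row(start = "2016-03-09 08:00", stop = "2016-03-09 14:00"))
  r <- classify_procedure(co$procedures[1, ], co, lex, final_variant())
  expect_false(r$text_hit); expect_true(r$order_hit); expect_true(r$final_flag)
  # all sources miss
  co2 <- one_case_cohort(p_row())
  r2 <- classify_procedure(co2$procedures[1, ], co2, lex, final_variant())
  expect_false(r2$final_flag)
  expect_equal(nrow(r2$evidence$text), 0)
  # disabled sources report FALSE with empty evidence
  expect_false(classify_procedure(co$procedures[1, ], co, lex,
                                  algorithm_variant())$order_hit)
})

test_that("cohort classification equals independently recomputed source flags", {
  co <- dedupe_procedures(generate_cohort(cohort_spec(n_procedures = 150, seed = 9)))
  lexd <- default_lexicon()
  fv <- final_variant()
  res <- classify_cohort(co, lexd, fv)
  m <- build_matcher(lexd, fv)
  for (i in seq_len(nrow(res))) {
    prow <- co$procedures[co$procedures$procedure_id == res$procedure_id[i], ]
    pid <- prow$patient_id
    t <- flag_text(prow, co$notes[co$notes$patient_id == pid, ], m, fv)$hit
    o <- flag_orders(prow, co$orders[co$orders$patient_id == pid, ], lexd, fv)$hit
    expect_equal(res$text_hit[i], t)
    expect_equal(res$order_hit[i], o)
    expect_equal(res$final_flag[i], t || o)
  }
  # results are a pure function of the set of rows, not their order
  shuf <- co
  set.seed(1)
  shuf$procedures <- shuf$procedures[sample(nrow(shuf$procedures)), ]
  shuf$notes <- shuf$notes[sample(nrow(shuf$notes)), ]
  shuf$orders <- shuf$orders[sample(nrow(shuf$orders)), ]
  res_shuf <- classify_cohort(shuf, lexd, fv)
  expect_equal(res_shuf[names(res_shuf) != "evidence"],
               res[names(res) != "evidence"])
  # determinism
  expect_equal(classify_cohort(co, lexd, fv), res)
})

test_that("source, filter and window monotonicity hold on a synthetic cohort", {
  co <- dedupe_procedures(generate_cohort(cohort_spec(n_procedures = 250, seed = 13)))
  lexd <- default_lexicon()
  flagged <- function(v) sum(classify_cohort(co, lexd, v)$final_flag)

  n_text <- flagged(algorithm_variant())
  n_orders <- flagged(algorithm_variant(use_text = FALSE, use_orders = TRUE))
  n_admin <- flagged(algorithm_variant(use_text = FALSE, use_admin = TRUE))
  n_to <- flagged(algorithm_variant(use_orders = TRUE))
  n_toa <- flagged(algorithm_variant(use_orders = TRUE, use_admin = TRUE))
  # enabling a source never decreases the flagged count
  expect_gte(n_to, max(n_text, n_orders))
  expect_gte(n_toa, max(n_to, n_admin))

  # adding any round-2 filter never increases the flagged count
  base <- algorithm_variant(use_orders = TRUE)
  for (v in list(algorithm_variant(use_orders = TRUE, exclude_oral_only = TRUE),
                 algorithm_variant(use_orders = TRUE,
                                   restrict_common_prophylaxis = TRUE),
                 algorithm_variant(use_orders = TRUE,
                                   max_order_duration_hours = 24),
                 algorithm_variant(use_orders = TRUE,
                                   exclude_same_day_post_procedure_orders = TRUE),
                 algorithm_variant(use_orders = TRUE,
                                   exclude_day_of_procedure_notes = TRUE))) {
    expect_lte(flagged(v), flagged(base))
  }

  # a 7-day window flags a superset of a 1-day window
  r7 <- classify_cohort(co, lexd, algorithm_variant(use_orders = TRUE,
                                                    window_days = 7))
  r1 <- classify_cohort(co, lexd, algorithm_variant(use_orders = TRUE,
                                                    window_days = 1))
  expect_true(all(r7$final_flag[r1$final_flag]))

  # scanned-note blindness: making every note unsearchable kills all text hits
  blind <- co
  blind$notes$is_searchable <- FALSE
  rb <- classify_cohort(blind, lexd, algorithm_variant())
  expect_false(any(rb$text_hit))
})
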