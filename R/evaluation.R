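#' Confusion counts
#'
#' @param tp,fp,tn,fn Non-negative integer counts of true positives, false
#'   positives, true negatives and false negatives.
#' @return An object of class `abx_confusion`.
#' @export
confusion_counts <- function(tp, fp, tn, fn) {
  v <- c(tp = tp, fp = fp, tn = tn, fn = fn)
  if (any(is.na(v)) || any(v < 0)) {
    abort_abx("confusion counts must be non-negative", "abx_validation_error")
  }
  structure(as.list(v), class = "abx_confusion")
}

#' @export
print.abx_confusion <- function(x, ...) {
  cat("<abx_confusion> tp:", x$tp, " fp:", x$fp, " tn:", x$tn, " fn:", x$fn, "\n")
  invisible(x)
}

#' Tally algorithm flags against gold labels
#'
#' Every classified procedure must carry exactly one gold label; counts
#' partition the cohort (tp + fn = gold positives, tn + fp = gold negatives).
#'
#' @param results An `abx_flag_results` tibble from [classify_cohort()] (any
#'   data frame with `procedure_id` and `final_flag` works).
#' @param labels A tibble with `procedure_id` and `prophylaxis_given`.
#' @return An `abx_confusion`.
#' @export
confusion <- function(results, labels) {
  if (is.null(labels)) {
    abort_abx("no gold labels supplied", "abx_validation_error")
  }
  lab <- labels$prophylaxis_given[match(results$procedure_id,
                                        labels$procedure_id)]
  if (anyNA(lab)) {
    missing_ids <- results$procedure_id[is.na(lab)]
    abort_abx(paste0("unlabeled procedure(s): ",
                     paste(utils::head(missing_ids, 10), collapse = ", "),
                     if (length(missing_ids) > 10) " ..."),
              "abx_validation_error")
  }
  flag <- results$final_flag
  confusion_counts(tp = sum(flag & lab), fp = sum(flag & !lab),
                   tn = sum(!flag & !lab), fn = sum(!flag & lab))
}

#' Performance metrics from confusion counts
#'
#' Computes the four standard metrics: sensitivity `tp/(tp+fn)`, specificity
#' `tn/(tn+fp)`, positive predictive value `tp/(tp+fp)` and negative
#' predictive value `tn/(tn+fn)`, plus the flagged count `tp+fp` and flagged
#' fraction `(tp+fp)/n_total`. A metric whose denominator is zero is reported
#' as `NA` (undefined) — never silently 0.
#'
#' @param counts An `abx_confusion`.
#' @param n_total Total procedures; must equal `tp+fp+tn+fn`.
#' @return A list of class `abx_metrics`.
#' @export
compute_metrics <- function(counts, n_total = NULL) {
  s <- counts$tp + counts$fp + counts$tn + counts$fn
  if (is.null(n_total)) n_total <- s
  if (n_total != s) {
    abort_abx(paste0("n_total (", n_total, ") does not equal tp+fp+tn+fn (",
                     s, ")"), "abx_validation_error")
  }
  ratio <- function(num, den) if (den > 0) num / den else NA_real_
  structure(list(
    sensitivity = ratio(counts$tp, counts$tp + counts$fn),
    specificity = ratio(counts$tn, counts$tn + counts$fp),
    ppv = ratio(counts$tp, counts$tp + counts$fp),
    npv = ratio(counts$tn, counts$tn + counts$fn),
    flagged_count = counts$tp + counts$fp,
    flagged_fraction = ratio(counts$tp + counts$fp, n_total),
    n_total = n_total,
    n_gold_positive = counts$tp + counts$fn,
    n_gold_negative = counts$tn + counts$fp,
    counts = counts
  ), class = "abx_metrics")
}

#' @export
print.abx_metrics <- function(x, ...) {
  pct <- function(v) if (is.na(v)) "undefined" else sprintf("%.1f%%", 100 * v)
  cat("<abx_metrics> n =", x$n_total,
      "(", x$n_gold_positive, "gold+, ", x$n_gold_negative, "gold-)\n")
  cat("  flagged:    ", x$flagged_count, sprintf("(%s)", pct(x$flagged_fraction)), "\n")
  cat("  sensitivity:", pct(x$sensitivity), " specificity:", pct(x$specificity), "\n")
  cat("  PPV:        ", pct(x$ppv), " NPV:        ", pct(x$npv), "\n")
  invisible(x)
}

#' Evaluate several algorithm variants on one labeled cohort
#'
#' Classifies the cohort under each variant and tabulates the metrics in a
#' development-grid layout, one row per variant in input order.
#'
#' @param cohort A labeled, deduplicated `abx_cohort`.
#' @param lex An `abx_lexicon`.
#' @param variants Named list of [algorithm_variant()] objects (e.g.
#'   [variant_presets()]).
#' @param same_day_policy See [flag_orders()].
#' @return A tibble: `variant`, `flagged`, `flagged_pct`, `ppv`, `npv`,
#'   `sensitivity`, `specificity`, `tp`, `fp`, `tn`, `fn`.
#' @export
variant_sweep <- function(cohort, lex, variants,
                          same_day_policy = c("include", "exclude")) {
  same_day_policy <- match.arg(same_day_policy)
  if (is.null(cohort$labels)) {
    abort_abx("variant_sweep requires a labeled cohort", "abx_validation_error")
  }
  rows <- lapply(seq_along(variants), function(i) {
    res <- classify_cohort(cohort, lex, variants[[i]], same_day_policy)
    m <- compute_metrics(confusion(res, cohort$labels))
    tibble::tibble(
      variant = names(variants)[i] %||% variants[[i]]$name %||% paste0("v", i),
      flagged = m$flagged_count,
      flagged_pct = 100 * m$flagged_fraction,
      ppv = m$ppv, npv = m$npv,
      sensitivity = m$sensitivity, specificity = m$specificity,
      tp = m$counts$tp, fp = m$counts$fp, tn = m$counts$tn, fn = m$counts$fn)
  })
  dplyr::bind_rows(rows)
}

#' Facility-level compliance stratification
#'
#' Computes, for each facility meeting the minimum procedure volume, the
#' fraction of its procedures flagged positive, banded as `high` (> 80%),
#' `middle` (60–80%, bounds included) or `low` (< 60%). Low-band facilities
#' deserve scrutiny of documentation practice (e.g. reliance on scanned
#' hand-written notes) before being read as true poor compliance.
#'
#' @param results An `abx_flag_results` tibble.
#' @param cohort The `abx_cohort` the results came from (supplies
#'   `facility_id`).
#' @param min_volume Minimum per-facility procedure count (default 50).
#' @return A tibble: `facility_id`, `n_procedures`, `n_flagged`,
#'   `compliance_rate`, `band`.
#' @export
stratify_by_facility <- function(results, cohort, min_volume = 50) {
  fac <- cohort$procedures$facility_id[
    match(results$procedure_id, cohort$procedures$procedure_id)]
  if (anyNA(fac)) {
    abort_abx("results contain procedures absent from the cohort",
              "abx_validation_error")
  }
  df <- tibble::tibble(facility_id = fac, flagged = results$final_flag)
  out <- dplyr::summarise(dplyr::group_by(df, .data$facility_id),
                          n_procedures = dplyr::n(),
                          n_flagged = sum(.data$flagged),
                          .groups = "drop")
  out <- out[out$n_procedures >= min_volume, , drop = FALSE]
  out$compliance_rate <- out$n_flagged / out$n_procedures
  out$band <- compliance_band(out$compliance_rate)
  dplyr::arrange(out, .data$facility_id)
}

#' Band a compliance rate
#'
#' @param rate Numeric vector of proportions in \[0, 1\].
#' @return Character vector: `"high"` (> 0.8), `"middle"` (\[0.6, 0.8\]) or
#'   `"low"` (< 0.6).
#' @export
compliance_band <- function(rate) {
  ifelse(rate > 0.8, "high", ifelse(rate >= 0.6, "middle", "low"))
}
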