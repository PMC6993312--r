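#' Configure a detection-algorithm variant
#'
#' An algorithm variant selects which EMR data sources are consulted and which
#' refinement filters are active. A procedure is flagged as having received
#' pre-incisional prophylaxis when any enabled source fires (logical OR).
#'
#' @param use_text Search electronic clinical notes for antimicrobial names.
#' @param use_orders Use computerized-order-entry antimicrobial orders.
#' @param use_admin Use barcode medication-administration records.
#' @param exclude_oral_only Drop agents available only in oral formulation
#'   (from every source): oral agents mentioned around a procedure are usually
#'   post-procedure courses, not pre-incisional prophylaxis.
#' @param restrict_common_prophylaxis Drop agents rarely used for prophylaxis
#'   (typically agents prescribed to treat unrelated infections).
#' @param max_order_duration_hours When set, an order with a recorded stop
#'   time only counts if its duration is strictly below this many hours;
#'   treatment courses for unrelated infections run longer than single
#'   pre-incisional doses. Orders without a stop time pass the filter.
#' @param exclude_same_day_post_procedure_orders Drop orders placed on the
#'   procedure date but after the procedure time: post-procedure
#'   antimicrobials are guideline-discordant and must not earn prophylaxis
#'   credit.
#' @param exclude_day_of_procedure_notes Shrink the note window to end the day
#'   before the procedure.
#' @param include_prophylaxis_term Also match the bare word "prophylaxis" in
#'   notes, as a nonspecific pseudo-agent.
#' @param window_days Look-back window in days before the procedure date
#'   (default 7, matching common practice of entering the pre-procedural
#'   antimicrobial at a visit up to a week ahead).
#' @param name Optional label used in sweep reports.
#' @return An object of class `abx_variant` (a named list of the settings).
#' @seealso [final_variant()], [variant_presets()]
#' @export
algorithm_variant <- function(use_text = TRUE,
                              use_orders = FALSE,
                              use_admin = FALSE,
                              exclude_oral_only = FALSE,
                              restrict_common_prophylaxis = FALSE,
                              max_order_duration_hours = NULL,
                              exclude_same_day_post_procedure_orders = FALSE,
                              exclude_day_of_procedure_notes = FALSE,
                              include_prophylaxis_term = FALSE,
                              window_days = 7L,
                              name = NULL) {
  if (!any(use_text, use_orders, use_admin)) {
    abort_abx("variant must enable at least one of text/orders/admin sources",
              "abx_validation_error")
  }
  window_days <- as.integer(window_days)
  if (is.na(window_days) || window_days < 1L) {
    abort_abx("window_days must be a positive integer", "abx_validation_error")
  }
  if (!is.null(max_order_duration_hours)) {
    max_order_duration_hours <- as.numeric(max_order_duration_hours)
    if (is.na(max_order_duration_hours) || max_order_duration_hours <= 0) {
      abort_abx("max_order_duration_hours must be positive or NULL",
                "abx_validation_error")
    }
  }
  structure(list(
    use_text = isTRUE(use_text),
    use_orders = isTRUE(use_orders),
    use_admin = isTRUE(use_admin),
    exclude_oral_only = isTRUE(exclude_oral_only),
    restrict_common_prophylaxis = isTRUE(restrict_common_prophylaxis),
    max_order_duration_hours = max_order_duration_hours,
    exclude_same_day_post_procedure_orders =
      isTRUE(exclude_same_day_post_procedure_orders),
    exclude_day_of_procedure_notes = isTRUE(exclude_day_of_procedure_notes),
    include_prophylaxis_term = isTRUE(include_prophylaxis_term),
    window_days = window_days,
    name = name
  ), class = "abx_variant")
}

#' @export
print.abx_variant <- function(x, ...) {
  srcs <- c("text", "orders", "admin")[c(x$use_text, x$use_orders, x$use_admin)]
  cat("<abx_variant>", x$name %||% "(unnamed)", "\n")
  cat("  sources:", paste(srcs, collapse = " + "),
      " window:", x$window_days, "days\n")
  filt <- c(
    if (x$exclude_oral_only) "exclude oral-only agents",
    if (x$restrict_common_prophylaxis) "common-prophylaxis agents only",
    if (!is.null(x$max_order_duration_hours))
      paste0("order duration < ", x$max_order_duration_hours, " h"),
    if (x$exclude_same_day_post_procedure_orders)
      "exclude same-day post-procedure orders",
    if (x$exclude_day_of_procedure_notes) "exclude day-of-procedure notes",
    if (x$include_prophylaxis_term) "include bare 'prophylaxis' term"
  )
  if (length(filt)) cat("  filters:", paste(filt, collapse = "; "), "\n")
  invisible(x)
}

#' The final refined algorithm variant
#'
#' Text note searches combined with medication orders, with the second-round
#' refinements: oral-only agents excluded, the agent list restricted to common
#' prophylaxis medications, orders limited to durations under 24 hours,
#' same-day post-procedure orders excluded, day-of-procedure notes retained,
#' the bare "prophylaxis" term not used, and a 7-day look-back window.
#'
#' @return An `abx_variant`.
#' @export
final_variant <- function() {
  algorithm_variant(
    use_text = TRUE, use_orders = TRUE, use_admin = FALSE,
    exclude_oral_only = TRUE,
    restrict_common_prophylaxis = TRUE,
    max_order_duration_hours = 24,
    exclude_same_day_post_procedure_orders = TRUE,
    exclude_day_of_procedure_notes = FALSE,
    include_prophylaxis_term = FALSE,
    window_days = 7L,
    name = "final"
  )
}

#' Named presets for every development-stage variant
#'
#' One preset per row of the iterative development grid: the three single
#' sources, their pairwise/three-way combinations, and the second-round
#' refinements (oral exclusion on text searches, common-agent restriction,
#' day-of-note exclusion, the bare "prophylaxis" term), plus `final`.
#'
#' @return A named list of `abx_variant` objects.
#' @export
variant_presets <- function() {
  v <- function(...) algorithm_variant(...)
  list(
    text = v(use_text = TRUE, name = "text"),
    orders = v(use_text = FALSE, use_orders = TRUE, name = "orders"),
    admin = v(use_text = FALSE, use_admin = TRUE, name = "admin"),
    text_orders = v(use_text = TRUE, use_orders = TRUE, name = "text_orders"),
    text_admin = v(use_text = TRUE, use_admin = TRUE, name = "text_admin"),
    orders_admin = v(use_text = FALSE, use_orders = TRUE, use_admin = TRUE,
                     name = "orders_admin"),
    text_orders_admin = v(use_text = TRUE, use_orders = TRUE, use_admin = TRUE,
                          name = "text_orders_admin"),
    text_excl_oral = v(use_text = TRUE, exclude_oral_only = TRUE,
                       name = "text_excl_oral"),
    common_agents = v(use_text = TRUE, use_orders = TRUE,
                      exclude_oral_only = TRUE,
                      restrict_common_prophylaxis = TRUE,
                      name = "common_agents"),
    excl_day_of_notes = v(use_text = TRUE,
                          exclude_day_of_procedure_notes = TRUE,
                          name = "excl_day_of_notes"),
    prophylaxis_term = v(use_text = TRUE, use_orders = TRUE,
                         include_prophylaxis_term = TRUE,
                         name = "prophylaxis_term"),
    final = final_variant()
  )
}
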