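#' Run the full double-check and assemble a run report
#'
#' Convenience wrapper tying the stages together: clean the pairs,
#' resolve and match them through the terminology backend, classify and
#' label, and aggregate into both evaluation modes — total pairs (a
#' static alerting system that fires on every occurrence) and unique
#' ordered NDC pairs (a learning system that adjudicates each distinct
#' pair once).
#'
#' @param pairs record-pair tibble (see [load_pairs()]).
#' @param backend terminology backend.
#' @param signal_words,strict_ndc passed to [clean_pairs()].
#' @param ground_truth optional ground-truth table for synthetic runs
#'   (see [check_pairs()]).
#' @param top_k rows in the frequency table.
#' @return A `rx_run_report` list: `cleaning` (funnel tibble),
#'   `outcomes` (per-pair tibble), `n_missing_rxcui`, `category_counts`
#'   (tibble of mismatch categories), `matrix_total`, `matrix_unique`
#'   (error matrices), `metrics` (two-row tibble), `alert_budget_total`,
#'   `alert_budget_unique`, `frequency` (top matched clinical drugs).
#' @export
run_check <- function(pairs, backend,
                      signal_words = c("duplicate", "cancel", "wrong",
                                       "denied"),
                      strict_ndc = FALSE, ground_truth = NULL,
                      top_k = 5L) {
  cleaned <- clean_pairs(pairs, signal_words = signal_words,
                         strict_ndc = strict_ndc)
  outcomes <- check_pairs(cleaned$pairs, backend,
                          ground_truth = ground_truth)
  analyzable <- outcomes[outcomes$status != "MISSING_RXCUI", , drop = FALSE]
  uniq <- dedupe_pairs(analyzable)

  m_total <- error_matrix(analyzable)
  m_unique <- error_matrix(uniq)
  metrics <- dplyr::bind_rows(
    compute_metrics(m_total, mode = "total"),
    compute_metrics(m_unique, mode = "unique")
  )
  cats <- analyzable$category[!is.na(analyzable$category)]
  category_counts <- tibble::tibble(
    category = MISMATCH_CATEGORIES,
    n = vapply(MISMATCH_CATEGORIES, function(k) sum(cats == k), integer(1))
  )
  structure(
    list(
      cleaning = cleaned$report,
      outcomes = outcomes,
      n_missing_rxcui = sum(outcomes$status == "MISSING_RXCUI"),
      category_counts = category_counts,
      matrix_total = m_total,
      matrix_unique = m_unique,
      metrics = metrics,
      alert_budget_total = alert_budget(m_total),
      alert_budget_unique = alert_budget(m_unique),
      frequency = frequency_report(analyzable, backend, top_k = top_k,
                                   n_total = nrow(outcomes))
    ),
    class = "rx_run_report"
  )
}

#' @export
print.rx_run_report <- function(x, ...) {
  cat(format_run_report(x), sep = "\n")
  invisible(x)
}

#' Format a run report as structured text
#'
#' Key-value funnel counts, the mismatch-category table, both error
#' matrices, both metric panels (metrics printed to 5 decimals,
#' percentages to 2 — the package's reporting precision), alert budgets
#' and the top matched clinical drugs.
#'
#' @param report an `rx_run_report` from [run_check()].
#' @return Character vector of report lines.
#' @export
format_run_report <- function(report) {
  f5 <- function(x) ifelse(is.na(x), "undefined", sprintf("%.5f", x))
  cl <- report$cleaning
  lines <- c(
    "== cleaning funnel ==",
    sprintf("input_pairs: %d", cl$n_input),
    sprintf("removed_signal_words: %d", cl$n_removed_signal_words),
    sprintf("removed_missing_ndc: %d", cl$n_removed_missing_ndc),
    sprintf("removed_invalid_ndc: %d", cl$n_removed_invalid_ndc),
    sprintf("retained: %d (%.2f%%)", cl$n_retained,
            retained_percent(cl$n_retained, max(cl$n_input, 1L))),
    sprintf("missing_rxcui_pairs: %d (excluded from matrices)",
            report$n_missing_rxcui),
    "",
    "== mismatch categories ==",
    sprintf("%-26s %d", report$category_counts$category,
            report$category_counts$n),
    ""
  )
  for (mode in c("total", "unique")) {
    m <- report[[paste0("matrix_", mode)]]
    met <- report$metrics[report$metrics$mode == mode, ]
    budget <- report[[paste0("alert_budget_", mode)]]
    lines <- c(lines,
      sprintf("== %s pairs (n=%d) ==", mode, sum(m)),
      sprintf("TP=%d FP=%d FN=%d TN=%d", m["tp"], m["fp"], m["fn"],
              m["tn"]),
      sprintf("accuracy: %s", f5(met$accuracy)),
      sprintf("sensitivity/recall: %s", f5(met$sensitivity)),
      sprintf("false_positive_rate: %s", f5(met$false_positive_rate)),
      sprintf("specificity: %s", f5(met$specificity)),
      sprintf("precision: %s", f5(met$precision)),
      sprintf("f1: %s", f5(met$f1)),
      sprintf("alerts_per_true_positive: %s",
              ifelse(is.na(budget), "undefined", as.character(budget))),
      "")
  }
  if (nrow(report$frequency)) {
    lines <- c(lines, "== most frequent matched clinical drugs ==",
               sprintf("%s  %s  %d (%.2f%%)", report$frequency$rxcui,
                       ifelse(is.na(report$frequency$name), "-",
                              report$frequency$name),
                       report$frequency$n, report$frequency$percent))
  }
  lines
}

#' Write per-pair outcomes as delimited text
#'
#' @param outcomes tibble from [check_pairs()].
#' @param path output file (tab-separated).
#' @return `path`, invisibly.
#' @export
write_outcomes <- function(outcomes, path) {
  flat <- outcomes
  flat$rx_scds <- vapply(outcomes$rx_scds, paste, character(1),
                         collapse = ",")
  flat$disp_scds <- vapply(outcomes$disp_scds, paste, character(1),
                           collapse = ",")
  readr::write_tsv(flat, path, progress = FALSE)
  invisible(path)
}
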