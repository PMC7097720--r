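#' Reduce outcomes to unique ordered NDC pairs
#'
#' A learning alerting system adjudicates each distinct
#' (prescribed NDC, dispensed NDC) combination once and suppresses
#' repeats, so its performance is evaluated over unique pairs. Keeps the
#' first occurrence of each ordered pair; `(A,B)` and `(B,A)` are
#' distinct, since prescribing A and dispensing B is a different event
#' from the reverse.
#'
#' @param outcomes tibble from [check_pairs()] (any tibble with `rx_ndc`
#'   and `disp_ndc` columns).
#' @return The subset of rows with the first occurrence of each ordered
#'   NDC pair.
#' @export
dedupe_pairs <- function(outcomes) {
  key <- paste(outcomes$rx_ndc, outcomes$disp_ndc, sep = "|")
  outcomes[!duplicated(key), , drop = FALSE]
}

#' Build an error matrix from labeled outcomes
#'
#' Counts outcomes by error-matrix label. Pairs without a label (missing
#' concept) are excluded from the matrix — they never reached the
#' comparison, mirroring their exclusion from performance evaluation.
#'
#' @param outcomes tibble with a `label` column, or omitted when the
#'   counts are given directly.
#' @param tp,fp,fn,tn direct counts (used when `outcomes` is missing).
#' @return An object of class `error_matrix`: named integer vector with
#'   `tp`, `fp`, `fn`, `tn`.
#' @examples
#' error_matrix(tp = 4, fp = 546, fn = 0, tn = 526459)
#' @export
error_matrix <- function(outcomes = NULL, tp = 0, fp = 0, fn = 0, tn = 0) {
  if (!is.null(outcomes)) {
    lab <- outcomes$label[!is.na(outcomes$label)]
    tp <- sum(lab == "TP")
    fp <- sum(lab == "FP")
    fn <- sum(lab == "FN")
    tn <- sum(lab == "TN")
  }
  m <- c(tp = as.integer(tp), fp = as.integer(fp), fn = as.integer(fn),
         tn = as.integer(tn))
  if (any(m < 0)) rx_abort("rxmatch_config_error", "negative matrix count")
  structure(m, class = "error_matrix")
}

#' @export
print.error_matrix <- function(x, ...) {
  cat(sprintf("<error_matrix> TP=%d FP=%d FN=%d TN=%d (n=%d)\n",
              x["tp"], x["fp"], x["fn"], x["tn"], sum(x)))
  invisible(x)
}

#' Performance metrics of the double-check from an error matrix
#'
#' Computes the six standard metrics:
#' accuracy \eqn{(TP+TN)/n}, sensitivity/recall \eqn{TP/(TP+FN)},
#' false-positive rate \eqn{FP/(FP+TN)}, specificity \eqn{TN/(FP+TN)},
#' precision \eqn{TP/(TP+FP)} and F1
#' \eqn{2 \cdot precision \cdot recall / (precision + recall)}.
#' A metric whose denominator is zero is `NA` (undefined), not an error.
#' Values are kept at full precision; use [format()] or round to 5
#' decimals for reporting.
#'
#' @param m an [error_matrix()].
#' @param mode evaluation mode tag carried into the report: `"total"`
#'   (static alerting, every occurrence alerts) or `"unique"` (learning
#'   alerting over unique NDC pairs).
#' @return A one-row tibble: `mode`, `n_pairs`, `accuracy`,
#'   `sensitivity`, `false_positive_rate`, `specificity`, `precision`,
#'   `f1`.
#' @export
compute_metrics <- function(m, mode = c("total", "unique")) {
  stopifnot(inherits(m, "error_matrix"))
  mode <- match.arg(mode)
  tp <- as.numeric(m["tp"]); fp <- as.numeric(m["fp"])
  fn <- as.numeric(m["fn"]); tn <- as.numeric(m["tn"])
  n <- tp + fp + fn + tn
  div <- function(num, den) if (den > 0) num / den else NA_real_
  precision <- div(tp, tp + fp)
  sensitivity <- div(tp, tp + fn)
  f1 <- if (!is.na(precision) && !is.na(sensitivity) &&
            (precision + sensitivity) > 0) {
    2 * precision * sensitivity / (precision + sensitivity)
  } else NA_real_
  tibble::tibble(
    mode = mode,
    n_pairs = as.integer(n),
    accuracy = div(tp + tn, n),
    sensitivity = sensitivity,
    false_positive_rate = div(fp, fp + tn),
    specificity = div(tn, fp + tn),
    precision = precision,
    f1 = f1
  )
}

#' Alerts per clinically significant alert
#'
#' The alert budget: how many alerts fire for each one that matters,
#' \eqn{(TP+FP)/TP}, rounded half-up to an integer. Comparing the budget
#' of the total-pair (static) matrix with the unique-pair (learning)
#' matrix quantifies how much alert fatigue a learning alert policy
#' would remove.
#'
#' @param m an [error_matrix()] with `tp > 0`.
#' @return Integer number of alerts per true positive; `NA` if `tp == 0`.
#' @examples
#' alert_budget(error_matrix(tp = 4, fp = 546))  # 137.5 -> 138
#' alert_budget(error_matrix(tp = 4, fp = 90))   # 23.5  -> 24
#' @export
alert_budget <- function(m) {
  stopifnot(inherits(m, "error_matrix"))
  tp <- as.numeric(m["tp"]); fp <- as.numeric(m["fp"])
  if (tp == 0) return(NA_integer_)
  as.integer(floor((tp + fp) / tp + 0.5))  # half-up, not banker's rounding
}

#' Most frequent matched clinical drugs
#'
#' Ranks the clinical-drug concepts of matching pairs by how often they
#' were dispensed, with the share of all analyzed pairs to two decimals.
#' For a pair whose sides share several concepts, the smallest shared
#' rxcui names the pair. Ties in count are broken by ascending rxcui.
#'
#' @param outcomes tibble from [check_pairs()].
#' @param backend optional terminology backend used to attach concept
#'   names.
#' @param top_k number of rows to keep (default 5).
#' @param n_total denominator for the percentage; defaults to
#'   `nrow(outcomes)` (all analyzed pairs, including those without a
#'   concept).
#' @return A tibble `rxcui`, `name`, `n`, `percent`, ordered by
#'   descending count.
#' @export
frequency_report <- function(outcomes, backend = NULL, top_k = 5L,
                             n_total = nrow(outcomes)) {
  matched <- outcomes[!is.na(outcomes$status) & outcomes$status == "MATCH", ,
                      drop = FALSE]
  if (!nrow(matched)) {
    return(tibble::tibble(rxcui = character(), name = character(),
                          n = integer(), percent = numeric()))
  }
  scd <- vapply(seq_len(nrow(matched)), function(i) {
    shared <- intersect(matched$rx_scds[[i]], matched$disp_scds[[i]])
    sort(shared)[1L]
  }, character(1))
  counts <- table(scd)
  out <- tibble::tibble(rxcui = names(counts), n = as.integer(counts))
  out <- out[order(-out$n, out$rxcui), , drop = FALSE]
  out <- head(out, top_k)
  out$name <- NA_character_
  if (!is.null(backend) && inherits(backend, "rx_fixture_backend")) {
    out$name <- vapply(out$rxcui, function(id) {
      row <- concept_row(backend, id)
      if (is.null(row)) NA_character_ else row$name
    }, character(1), USE.NAMES = FALSE)
  }
  out$percent <- round(100 * out$n / n_total, 2)
  out[, c("rxcui", "name", "n", "percent")]
}
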