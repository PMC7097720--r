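#' Load paired e-prescription / dispensing records
#'
#' Reads a delimited text file (comma or tab, auto-detected from the
#' header line unless `delim` is given) with one row per
#' e-prescription/dispensing event. Required columns: `rx_name`, `rx_ndc`,
#' `disp_name`, `disp_ndc`; optional: `pair_id` (generated from the row
#' number when absent) and `prescriber_id`.
#'
#' @param path input file.
#' @param delim field delimiter, or `NULL` to auto-detect.
#' @return A tibble of record pairs in file order with columns `pair_id`,
#'   `rx_name`, `rx_ndc`, `disp_name`, `disp_ndc`, `prescriber_id`.
#' @export
load_pairs <- function(path, delim = NULL) {
  if (!file.exists(path))
    rx_abort("rxmatch_format_error", sprintf("input file not found: %s", path))
  if (is.null(delim)) {
    hdr <- readLines(path, n = 1L)
    delim <- if (grepl("\t", hdr, fixed = TRUE)) "\t" else ","
  }
  df <- readr::read_delim(path, delim = delim,
                          col_types = readr::cols(.default = "c"),
                          na = character(), progress = FALSE)
  required <- c("rx_name", "rx_ndc", "disp_name", "disp_ndc")
  miss <- setdiff(required, names(df))
  if (length(miss))
    rx_abort("rxmatch_format_error",
             sprintf("missing required columns: %s",
                     paste(miss, collapse = ", ")))
  if (!"pair_id" %in% names(df)) {
    df$pair_id <- sprintf("pair%06d", seq_len(nrow(df)))
  }
  if (!"prescriber_id" %in% names(df)) df$prescriber_id <- NA_character_
  if (anyDuplicated(df$pair_id))
    rx_abort("rxmatch_format_error", "pair_id values are not unique")
  df[, c("pair_id", "rx_name", "rx_ndc", "disp_name", "disp_ndc",
         "prescriber_id")]
}

#' Clean record pairs and report the funnel
#'
#' Applies the filtering rules used before terminology lookup, in order:
#'
#' 1. remove pairs whose prescribed or dispensed free-text name contains a
#'    signal word (case-insensitive substring, so inflections such as
#'    "CANCELLED" are caught) — these annotations mark invalid pairs such
#'    as duplicated or reversed transactions;
#' 2. remove pairs with a missing/blank NDC on either side;
#' 3. if `strict_ndc`, additionally remove pairs whose NDC fails 11-digit
#'    normalization; otherwise such pairs are retained and will surface in
#'    the missing-concept stream of the matcher (malformed representative
#'    NDCs are themselves a data signal worth counting there).
#'
#' @param pairs tibble from [load_pairs()].
#' @param signal_words words marking invalid pairs; matching is
#'   case-insensitive substring over both name fields.
#' @param strict_ndc drop structurally invalid NDCs during cleaning
#'   instead of routing them forward as unresolvable.
#' @return A list with `pairs` (the retained rows, input order preserved)
#'   and `report`, a one-row tibble with the funnel counts `n_input`,
#'   `n_removed_signal_words`, `n_removed_missing_ndc`,
#'   `n_removed_invalid_ndc`, `n_retained` (counts always sum to
#'   `n_input`).
#' @export
clean_pairs <- function(pairs,
                        signal_words = c("duplicate", "cancel", "wrong",
                                         "denied"),
                        strict_ndc = FALSE) {
  stopifnot(length(signal_words) >= 1L)
  n_input <- nrow(pairs)

  pat <- paste(vapply(tolower(signal_words), rescape, character(1)),
               collapse = "|")
  has_signal <- grepl(pat, tolower(paste(pairs$rx_name, pairs$disp_name)))
  removed_signal <- sum(has_signal)
  pairs <- pairs[!has_signal, , drop = FALSE]

  blank <- function(x) is.na(x) | !nzchar(trimws(x))
  missing_ndc <- blank(pairs$rx_ndc) | blank(pairs$disp_ndc)
  removed_missing <- sum(missing_ndc)
  pairs <- pairs[!missing_ndc, , drop = FALSE]

  removed_invalid <- 0L
  if (strict_ndc && nrow(pairs)) {
    ok <- normalize_ndc(pairs$rx_ndc, strict = FALSE)$valid &
      normalize_ndc(pairs$disp_ndc, strict = FALSE)$valid
    removed_invalid <- sum(!ok)
    pairs <- pairs[ok, , drop = FALSE]
  }

  report <- tibble::tibble(
    n_input = n_input,
    n_removed_signal_words = removed_signal,
    n_removed_missing_ndc = removed_missing,
    n_removed_invalid_ndc = removed_invalid,
    n_retained = nrow(pairs)
  )
  list(pairs = pairs, report = report)
}

rescape <- function(x) gsub("([][{}()+*^$|\\\\?.])", "\\\\\\1", x)

#' Retained fraction of a cleaning funnel
#'
#' Percentage of input pairs that survive cleaning, printed to two
#' decimals — the headline number of a cleaning-funnel report.
#'
#' @param n_retained,n_input counts.
#' @return Percentage rounded to 2 decimals.
#' @examples
#' retained_percent(527881, 537710)
#' @export
retained_percent <- function(n_retained, n_input) {
  round(100 * n_retained / n_input, 2)
}
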