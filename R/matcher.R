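#' @rdname match_pair
#' @format NULL
#' @export
MISMATCH_CATEGORIES <- c("DIFFERENT_INGREDIENT", "DIFFERENT_STRENGTH",
                         "DIFFERENT_PACK_QUANTITY", "DIFFERENT_FORM",
                         "OUTSIDE_RXNORM", "OTHER_QUALITATIVE")

#' Match the resolved clinical-drug sets of a record pair
#'
#' The central comparison: the prescribed and dispensed NDCs have each
#' been resolved to a set of SCD-level concept identifiers, and the pair
#' is `MISSING_RXCUI` if either side resolved to nothing, `MATCH` if the
#' sets intersect, and `MISMATCH` otherwise. Non-empty intersection (not
#' set equality) is used because a branded concept can legitimately
#' resolve to several clinical drugs; any shared clinical-drug identity
#' means the same product was selected.
#'
#' @param rx_scds,disp_scds character vectors of SCD-level rxcuis (empty
#'   when resolution failed).
#' @return `"MISSING_RXCUI"`, `"MATCH"` or `"MISMATCH"`.
#' @examples
#' match_pair("830845", "314200")  # different drugs -> MISMATCH
#' match_pair("751620", "751620")  # same drug -> MATCH
#' match_pair(character(), "314200")  # unresolved -> MISSING_RXCUI
#' @export
match_pair <- function(rx_scds, disp_scds) {
  if (length(rx_scds) == 0L || length(disp_scds) == 0L) return("MISSING_RXCUI")
  if (length(intersect(rx_scds, disp_scds)) > 0L) "MATCH" else "MISMATCH"
}

#' Classify a mismatched pair into the clinical-significance taxonomy
#'
#' A decision cascade over the structured attributes of the two sides;
#' the first difference found, in severity order, names the category:
#'
#' 1. `OUTSIDE_RXNORM` — either side is uncurated (outside the
#'    terminology's curated scope), so attributes are unavailable and no
#'    finer comparison is possible;
#' 2. `DIFFERENT_INGREDIENT` — the ingredient sets differ;
#' 3. `DIFFERENT_STRENGTH` — same ingredients, any per-ingredient
#'    strength differs (exact value+unit comparison after unit
#'    canonicalization — case-fold and trim — with no unit conversion);
#' 4. `DIFFERENT_PACK_QUANTITY` — same ingredients and strengths, pack
#'    quantities differ (a pack vs a non-pack counts as different);
#' 5. `DIFFERENT_FORM` — dose forms differ;
#' 6. `OTHER_QUALITATIVE` — anything else (e.g. releasing-mechanism or
#'    sugar-free qualifiers).
#'
#' The severity ordering puts the most harmful difference first, so a
#' compound difference (ingredient and form) is named by its most harmful
#' component. When a side resolved to several clinical drugs, the
#' attributes of the lexicographically smallest rxcui on each side are
#' compared — a deterministic tie-break.
#'
#' @param attrs_rx,attrs_disp a single [`scd_attributes`][get_scd_attributes]
#'   object or a list of them (one per resolved SCD on that side).
#' @return One of [MISMATCH_CATEGORIES].
#' @export
classify_mismatch <- function(attrs_rx, attrs_disp) {
  ar <- as_attr_list(attrs_rx)
  ad <- as_attr_list(attrs_disp)
  if (any(!vapply(c(ar, ad), function(a) isTRUE(a$curated), logical(1)))) {
    return("OUTSIDE_RXNORM")
  }
  a <- smallest_attr(ar)
  b <- smallest_attr(ad)
  if (!isTRUE(a$curated) || length(a$ingredients) == 0L ||
      !isTRUE(b$curated) || length(b$ingredients) == 0L) {
    rx_abort("rxmatch_attribute_unavailable",
             "curated concept without usable attributes in classification")
  }
  if (!setequal(a$ingredients, b$ingredients)) return("DIFFERENT_INGREDIENT")
  if (!strengths_equal(a$strengths, b$strengths)) return("DIFFERENT_STRENGTH")
  qa <- a$pack_quantity
  qb <- b$pack_quantity
  if (!identical(is.na(qa), is.na(qb)) ||
      (!is.na(qa) && !is.na(qb) && qa != qb)) {
    return("DIFFERENT_PACK_QUANTITY")
  }
  if (!identical(a$dose_form, b$dose_form)) return("DIFFERENT_FORM")
  "OTHER_QUALITATIVE"
}

as_attr_list <- function(x) {
  if (inherits(x, "scd_attributes")) list(x) else x
}

smallest_attr <- function(lst) {
  ids <- vapply(lst, function(a) a$scd_rxcui, character(1))
  lst[[which.min(rank(ids, ties.method = "first"))]]
}

strengths_equal <- function(sa, sb) {
  keys <- union(names(sa), names(sb))
  for (k in keys) {
    a <- sa[[k]]
    b <- sb[[k]]
    if (is.null(a) || is.null(b)) return(FALSE)
    if (!isTRUE(all.equal(a$value, b$value)) ||
        !identical(canonical_unit(a$unit), canonical_unit(b$unit))) {
      return(FALSE)
    }
  }
  TRUE
}

#' Assign an error-matrix label to a match outcome
#'
#' Labels follow the clinical-significance scheme: a mismatch in
#' ingredient or strength could harm the patient and is a true positive
#' (`TP`); the remaining mismatch categories (pack quantity, form,
#' qualitative, outside the curated terminology) are alerts that would
#' typically not prevent harm, hence false positives (`FP`). A matching
#' pair is a true negative (`TN`) unless ground truth (available in
#' synthetic runs) says the drugs are in fact non-equivalent — a mapping
#' defect the check cannot see — which makes it a false negative (`FN`).
#' Pairs with a missing concept carry no label.
#'
#' @param status `"MATCH"` or `"MISMATCH"`.
#' @param category mismatch category (required when `status ==
#'   "MISMATCH"`).
#' @param truly_equivalent optional ground-truth flag for `MATCH` pairs.
#' @return `"TP"`, `"FP"`, `"TN"`, `"FN"`, or `NA` for `MISSING_RXCUI`.
#' @export
label_outcome <- function(status, category = NA_character_,
                          truly_equivalent = NA) {
  if (status == "MISSING_RXCUI") return(NA_character_)
  if (status == "MATCH") {
    return(if (isFALSE(truly_equivalent)) "FN" else "TN")
  }
  stopifnot(category %in% MISMATCH_CATEGORIES)
  if (category %in% c("DIFFERENT_INGREDIENT", "DIFFERENT_STRENGTH")) "TP"
  else "FP"
}
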