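#' Resolve a vector of raw NDCs through a terminology backend
#'
#' Normalizes each code and looks up its concept and SCD-level
#' resolution. Codes that fail normalization, are unknown to the
#' terminology, or belong to a branded concept with no related clinical
#' drug resolve to an empty set and carry a note saying why — these land
#' in the missing-concept stream of the matcher rather than halting the
#' run.
#'
#' @param backend a terminology backend.
#' @param ndcs character vector of raw NDC strings.
#' @return A tibble with one row per input: `ndc_raw`, `ndc11`
#'   (normalized or `NA`), `rxcui`, `tty`, `scds` (list column of
#'   character vectors), `note` (`"ok"`, `"invalid_ndc"`, `"no_rxcui"`,
#'   `"no_related_scd"`).
#' @export
resolve_ndcs <- function(backend, ndcs) {
  norm <- normalize_ndc(ndcs, strict = FALSE)
  n <- length(ndcs)
  rxcui <- rep(NA_character_, n)
  tty <- rep(NA_character_, n)
  scds <- rep(list(character()), n)
  note <- ifelse(norm$valid, "ok", "invalid_ndc")
  memo <- new.env(parent = emptyenv())
  for (i in seq_len(n)) {
    if (!norm$valid[i]) next
    key <- norm$normalized[i]
    hit <- memo[[key]]
    if (is.null(hit)) {
      concept <- ndc_to_concept(backend, key)
      if (is.null(concept)) {
        hit <- list(rxcui = NA_character_, tty = NA_character_,
                    scds = character(), note = "no_rxcui")
      } else {
        res <- tryCatch(
          resolve_to_scds(backend, concept),
          rxmatch_resolution_error = function(e) character()
        )
        hit <- list(rxcui = concept$rxcui, tty = concept$tty, scds = res,
                    note = if (length(res)) "ok" else "no_related_scd")
      }
      memo[[key]] <- hit
    }
    rxcui[i] <- hit$rxcui
    tty[i] <- hit$tty
    scds[[i]] <- hit$scds
    note[i] <- hit$note
  }
  tibble::tibble(ndc_raw = ndcs, ndc11 = norm$normalized, rxcui = rxcui,
                 tty = tty, scds = scds, note = note)
}

#' Run the automated double-check over cleaned record pairs
#'
#' For each record pair, resolves both NDCs to SCD-level concept sets,
#' matches them, classifies any mismatch into the clinical-significance
#' taxonomy, and assigns the error-matrix label. Resolution and matching
#' are memoized over distinct NDCs and distinct NDC pairs, so streams
#' dominated by repeat dispensing (the normal case for a pharmacy feed)
#' cost little more than their unique-pair content.
#'
#' @param pairs tibble of cleaned record pairs (see [clean_pairs()]).
#' @param backend a terminology backend.
#' @param ground_truth optional tibble with `pair_id` and
#'   `truly_equivalent` (logical): synthetic runs use it to surface false
#'   negatives — pairs whose concepts match only because of a defective
#'   NDC mapping.
#' @return A tibble of match outcomes: `pair_id`, `rx_ndc`, `disp_ndc`
#'   (normalized NDCs, raw when unnormalizable), `status`, `category`,
#'   `label`, `rx_scds`, `disp_scds` (list columns).
#' @export
check_pairs <- function(pairs, backend, ground_truth = NULL) {
  n <- nrow(pairs)
  if (n == 0L) {
    return(tibble::tibble(
      pair_id = character(), rx_ndc = character(), disp_ndc = character(),
      status = character(), category = character(), label = character(),
      rx_scds = list(), disp_scds = list()
    ))
  }
  uniq <- unique(c(pairs$rx_ndc, pairs$disp_ndc))
  res <- resolve_ndcs(backend, uniq)
  idx_rx <- match(pairs$rx_ndc, uniq)
  idx_disp <- match(pairs$disp_ndc, uniq)

  ndc_key <- ifelse(is.na(res$ndc11), res$ndc_raw, res$ndc11)
  scd_key <- vapply(res$scds, paste, character(1), collapse = ",")

  # one match/classify evaluation per distinct (rx, disp) resolution pair
  pair_key <- paste(scd_key[idx_rx], scd_key[idx_disp], sep = "|")
  first <- !duplicated(pair_key)
  attr_memo <- new.env(parent = emptyenv())
  get_attrs <- function(scds) {
    lapply(scds, function(id) {
      a <- attr_memo[[id]]
      if (is.null(a)) {
        a <- get_scd_attributes(backend, id)
        attr_memo[[id]] <- a
      }
      a
    })
  }
  status_map <- character(0)
  category_map <- character(0)
  for (i in which(first)) {
    rx_scds <- res$scds[[idx_rx[i]]]
    disp_scds <- res$scds[[idx_disp[i]]]
    st <- match_pair(rx_scds, disp_scds)
    cat_i <- NA_character_
    if (st == "MISMATCH") {
      cat_i <- classify_mismatch(get_attrs(rx_scds), get_attrs(disp_scds))
    }
    status_map[[pair_key[i]]] <- st
    category_map[[pair_key[i]]] <- cat_i
  }
  status <- unname(status_map[pair_key])
  category <- unname(category_map[pair_key])

  truly_equivalent <- rep(NA, n)
  if (!is.null(ground_truth)) {
    gt <- ground_truth$truly_equivalent[match(pairs$pair_id,
                                              ground_truth$pair_id)]
    truly_equivalent <- gt
  }
  # vectorized equivalent of label_outcome() row by row
  label <- rep(NA_character_, n)
  is_match <- status == "MATCH"
  label[is_match] <- ifelse(!is.na(truly_equivalent[is_match]) &
                              !truly_equivalent[is_match], "FN", "TN")
  is_mis <- status == "MISMATCH"
  label[is_mis] <- ifelse(
    category[is_mis] %in% c("DIFFERENT_INGREDIENT", "DIFFERENT_STRENGTH"),
    "TP", "FP")

  tibble::tibble(
    pair_id = pairs$pair_id,
    rx_ndc = ndc_key[idx_rx],
    disp_ndc = ndc_key[idx_disp],
    status = status,
    category = category,
    label = label,
    rx_scds = res$scds[idx_rx],
    disp_scds = res$scds[idx_disp]
  )
}
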