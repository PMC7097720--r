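#' Terminology backends
#'
#' A terminology backend resolves normalized 11-digit NDCs to drug concepts
#' and concepts to their semantic-clinical-drug (SCD) identifiers and
#' structured attributes. Two implementations satisfy the same contract:
#' a local fixture store built from four plain-text tables
#' ([terminology_fixture()]) and a client for the public RxNorm REST API
#' ([rxnorm_live_backend()]). All pipeline code is written against the
#' generics, so the two are interchangeable.
#'
#' @section Term types:
#' Concepts carry a term type (`tty`): `SCD` (semantic clinical drug —
#' ingredient + strength + dose form), `SBD` (its branded counterpart),
#' `GPCK`/`BPCK` (generic/branded packs bundling counted units), or
#' `OTHER`. Matching is performed at the generic clinical-drug level:
#' SCDs and generic packs stand for themselves, while branded concepts
#' (SBD, BPCK) are resolved to their related generic concepts. A generic
#' pack is the most specific generic identity of a pack product — two
#' packs of the same tablet in different counts are distinct clinical
#' drug concepts, which is exactly the distinction the pack-quantity
#' mismatch category needs.
#'
#' @param backend a terminology backend object.
#' @name terminology-backend
NULL

#' Resolve a normalized NDC to its drug concept
#'
#' Looks up the concept mapped to an 11-digit NDC. Obsolete NDCs and
#' remapped/retired concepts are followed to their current active concept
#' before being returned, so downstream comparison always sees current
#' identifiers. NDCs unknown to the terminology return `NULL` — a data
#' outcome, not an error.
#'
#' @inheritParams terminology-backend
#' @param ndc a single normalized 11-digit NDC string.
#' @return A one-row tibble (`rxcui`, `tty`, `name`, `status`, `curated`)
#'   or `NULL` if the NDC has no concept.
#' @export
ndc_to_concept <- function(backend, ndc) UseMethod("ndc_to_concept")

#' Resolve a concept to its semantic-clinical-drug identifiers
#'
#' SCDs and generic packs (GPCK) resolve to themselves; branded concepts
#' (SBD, BPCK) resolve to the set of related generic concepts recorded in
#' the terminology. Uncurated concepts (outside the curated scope of the
#' terminology) resolve to themselves and are flagged by their `curated`
#' field downstream. A branded concept with no related generic in the
#' snapshot signals `rxmatch_resolution_error`.
#'
#' @inheritParams terminology-backend
#' @param rxcui a concept identifier (or a one-row concept tibble as
#'   returned by [ndc_to_concept()]).
#' @return Character vector of SCD-level rxcuis (non-empty).
#' @export
resolve_to_scds <- function(backend, rxcui) UseMethod("resolve_to_scds")

#' Fetch structured attributes of an SCD-level concept
#'
#' Returns the ingredient set, per-ingredient strengths, dose form, pack
#' quantity and qualifier tags used by the mismatch classifier. Uncurated
#' concepts return a stub carrying only `curated = FALSE`; a curated
#' concept with no attribute rows is a snapshot integrity failure and
#' signals `rxmatch_attribute_unavailable`.
#'
#' @inheritParams terminology-backend
#' @param rxcui a single SCD or pack concept identifier.
#' @return An object of class `scd_attributes`: a list with `scd_rxcui`,
#'   `curated`, `ingredients` (character), `strengths` (named list of
#'   `list(value, unit)` keyed by ingredient), `dose_form`,
#'   `pack_quantity` (integer or `NA`), `qualifiers` (character).
#' @export
get_scd_attributes <- function(backend, rxcui) UseMethod("get_scd_attributes")

new_scd_attributes <- function(scd_rxcui, curated, ingredients = character(),
                               strengths = list(), dose_form = NA_character_,
                               pack_quantity = NA_integer_,
                               qualifiers = character()) {
  structure(
    list(scd_rxcui = scd_rxcui, curated = curated, ingredients = ingredients,
         strengths = strengths, dose_form = dose_form,
         pack_quantity = pack_quantity, qualifiers = qualifiers),
    class = "scd_attributes"
  )
}

#' @export
print.scd_attributes <- function(x, ...) {
  cat("<scd_attributes> rxcui", x$scd_rxcui,
      if (!x$curated) "(uncurated)" else "", "\n")
  if (x$curated) {
    str_txt <- vapply(x$ingredients, function(i) {
      s <- x$strengths[[i]]
      if (is.null(s)) i else sprintf("%s %s %s", i, s$value, s$unit)
    }, character(1))
    cat("  ingredients:", paste(str_txt, collapse = " / "), "\n")
    cat("  dose form:", x$dose_form,
        if (!is.na(x$pack_quantity)) sprintf("| pack of %d", x$pack_quantity)
        else "", "\n")
    if (length(x$qualifiers))
      cat("  qualifiers:", paste(x$qualifiers, collapse = ", "), "\n")
  }
  invisible(x)
}

# ---- fixture backend --------------------------------------------------

#' Build a fixture terminology backend from in-memory tables
#'
#' The fixture store is a snapshot of a drug terminology held in four
#' tables, mirroring what the live API serves: `concepts` (rxcui, tty,
#' name, status, remapped_to, curated), `ndc_map` (ndc11, rxcui,
#' ndc_status — at most one concept per NDC; the one-to-many relation runs
#' concept to many NDCs), `scd_attributes` (one row per rxcui x ingredient:
#' rxcui, ingredient, strength_value, strength_unit, dose_form,
#' pack_quantity, qualifiers — qualifiers semicolon-separated), and
#' `related` (rxcui, related_rxcui, relation).
#'
#' The backend is a pure function of its tables: identical tables give
#' identical answers.
#'
#' @param concepts,ndc_map,scd_attributes,related data frames with the
#'   columns above.
#' @return A backend of class `rx_fixture_backend`.
#' @seealso [read_terminology()] to load the same tables from TSV files,
#'   [write_terminology()] to serialize them.
#' @export
terminology_fixture <- function(concepts, ndc_map, scd_attributes, related) {
  concepts <- tibble::as_tibble(concepts)
  ndc_map <- tibble::as_tibble(ndc_map)
  scd_attributes <- tibble::as_tibble(scd_attributes)
  related <- tibble::as_tibble(related)

  need <- function(df, cols, what) {
    miss <- setdiff(cols, names(df))
    if (length(miss))
      rx_abort("rxmatch_format_error",
               sprintf("%s table missing columns: %s", what,
                       paste(miss, collapse = ", ")))
  }
  need(concepts, c("rxcui", "tty", "name", "status", "remapped_to", "curated"),
       "concepts")
  need(ndc_map, c("ndc11", "rxcui", "ndc_status"), "ndc_map")
  need(scd_attributes,
       c("rxcui", "ingredient", "strength_value", "strength_unit",
         "dose_form", "pack_quantity", "qualifiers"), "scd_attributes")
  need(related, c("rxcui", "related_rxcui", "relation"), "related")

  concepts$rxcui <- as.character(concepts$rxcui)
  concepts$remapped_to <- as.character(concepts$remapped_to)
  concepts$curated <- as.logical(concepts$curated)
  ndc_map$ndc11 <- as.character(ndc_map$ndc11)
  ndc_map$rxcui <- as.character(ndc_map$rxcui)
  scd_attributes$rxcui <- as.character(scd_attributes$rxcui)
  related$rxcui <- as.character(related$rxcui)
  related$related_rxcui <- as.character(related$related_rxcui)

  if (anyDuplicated(concepts$rxcui))
    rx_abort("rxmatch_format_error", "duplicate rxcui in concepts table")
  dup_ndc <- ndc_map$ndc11[duplicated(ndc_map$ndc11)]
  if (length(dup_ndc))
    rx_abort("rxmatch_format_error",
             sprintf("NDC mapped to more than one concept: %s", dup_ndc[1L]))
  remapped <- concepts[concepts$status == "remapped", ]
  if (nrow(remapped)) {
    tgt <- concepts$status[match(remapped$remapped_to, concepts$rxcui)]
    if (any(is.na(remapped$remapped_to)) || any(is.na(tgt)) ||
        any(tgt != "active"))
      rx_abort("rxmatch_format_error",
               "remapped concept without an active remap target")
  }

  structure(
    list(concepts = concepts, ndc_map = ndc_map,
         scd_attributes = scd_attributes, related = related),
    class = c("rx_fixture_backend", "rx_backend")
  )
}

#' @export
print.rx_fixture_backend <- function(x, ...) {
  cat(sprintf(
    "<rx_fixture_backend> %d concepts, %d NDC mappings, %d attribute rows\n",
    nrow(x$concepts), nrow(x$ndc_map), nrow(x$scd_attributes)))
  invisible(x)
}

concept_row <- function(backend, rxcui) {
  i <- match(rxcui, backend$concepts$rxcui)
  if (is.na(i)) return(NULL)
  backend$concepts[i, ]
}

# follow remapped_to links (retired/remapped concepts) to an active concept
follow_remap <- function(backend, row, depth = 0L) {
  if (is.null(row) || depth > 10L) return(row)
  if (!is.na(row$remapped_to) && nzchar(row$remapped_to) &&
      row$status != "active") {
    nxt <- concept_row(backend, row$remapped_to)
    if (!is.null(nxt)) return(follow_remap(backend, nxt, depth + 1L))
  }
  row
}

#' @export
ndc_to_concept.rx_fixture_backend <- function(backend, ndc) {
  stopifnot(length(ndc) == 1L)
  i <- match(as.character(ndc), backend$ndc_map$ndc11)
  if (is.na(i)) return(NULL)
  rxcui <- backend$ndc_map$rxcui[i]
  if (is.na(rxcui) || !nzchar(rxcui)) return(NULL)
  row <- concept_row(backend, rxcui)
  if (is.null(row)) return(NULL)
  row <- follow_remap(backend, row)
  row[, c("rxcui", "tty", "name", "status", "curated")]
}

#' @export
resolve_to_scds.rx_fixture_backend <- function(backend, rxcui) {
  if (is.data.frame(rxcui)) rxcui <- rxcui$rxcui
  stopifnot(length(rxcui) == 1L)
  row <- concept_row(backend, rxcui)
  if (is.null(row))
    rx_abort("rxmatch_unknown_concept",
             sprintf("concept %s not in snapshot", rxcui))
  row <- follow_remap(backend, row)
  if (row$tty %in% c("SCD", "GPCK") || !isTRUE(row$curated)) {
    return(row$rxcui)
  }
  rel <- backend$related[backend$related$rxcui == row$rxcui, ]
  rel_tty <- backend$concepts$tty[match(rel$related_rxcui,
                                        backend$concepts$rxcui)]
  scds <- rel$related_rxcui[!is.na(rel_tty) & rel_tty %in% c("SCD", "GPCK")]
  if (!length(scds))
    rx_abort("rxmatch_resolution_error",
             sprintf("%s concept %s has no related clinical drug",
                     row$tty, row$rxcui))
  sort(unique(scds))
}

#' @export
get_scd_attributes.rx_fixture_backend <- function(backend, rxcui) {
  stopifnot(length(rxcui) == 1L)
  row <- concept_row(backend, rxcui)
  if (is.null(row))
    rx_abort("rxmatch_unknown_concept",
             sprintf("concept %s not in snapshot", rxcui))
  if (!isTRUE(row$curated)) {
    return(new_scd_attributes(row$rxcui, curated = FALSE))
  }
  att <- backend$scd_attributes[backend$scd_attributes$rxcui == row$rxcui, ]
  if (!nrow(att))
    rx_abort("rxmatch_attribute_unavailable",
             sprintf("curated concept %s has no attribute rows", row$rxcui))
  att <- att[order(att$ingredient), ]
  strengths <- list()
  for (k in seq_len(nrow(att))) {
    if (!is.na(att$strength_value[k])) {
      strengths[[att$ingredient[k]]] <-
        list(value = att$strength_value[k],
             unit = canonical_unit(att$strength_unit[k]))
    }
  }
  quals <- att$qualifiers[1L]
  quals <- if (is.na(quals) || !nzchar(quals)) character() else
    sort(tolower(trimws(strsplit(quals, ";", fixed = TRUE)[[1L]])))
  new_scd_attributes(
    row$rxcui, curated = TRUE,
    ingredients = sort(unique(att$ingredient)),
    strengths = strengths,
    dose_form = tolower(trimws(att$dose_form[1L])),
    pack_quantity = if (is.na(att$pack_quantity[1L])) NA_integer_ else
      as.integer(att$pack_quantity[1L]),
    qualifiers = quals
  )
}

canonical_unit <- function(u) tolower(trimws(u))

# ---- table IO ---------------------------------------------------------

terminology_files <- c(
  concepts = "concepts.tsv", ndc_map = "ndc_map.tsv",
  scd_attributes = "scd_attributes.tsv", related = "related.tsv"
)

#' Read a fixture terminology from a directory of TSV tables
#'
#' Expects `concepts.tsv`, `ndc_map.tsv`, `scd_attributes.tsv` and
#' `related.tsv` (UTF-8, header row, fixed column order) as written by
#' [write_terminology()].
#'
#' @param dir directory containing the four tables.
#' @return A backend of class `rx_fixture_backend`.
#' @export
read_terminology <- function(dir) {
  paths <- file.path(dir, terminology_files)
  missing <- !file.exists(paths)
  if (any(missing))
    rx_abort("rxmatch_format_error",
             sprintf("terminology tables not found: %s",
                     paste(terminology_files[missing], collapse = ", ")))
  tb <- lapply(paths, function(p)
    readr::read_tsv(p, col_types = readr::cols(.default = "c"),
                    progress = FALSE))
  names(tb) <- names(terminology_files)
  tb$concepts$curated <- as.logical(tb$concepts$curated)
  tb$scd_attributes$strength_value <-
    as.numeric(tb$scd_attributes$strength_value)
  tb$scd_attributes$pack_quantity <-
    as.integer(tb$scd_attributes$pack_quantity)
  terminology_fixture(tb$concepts, tb$ndc_map, tb$scd_attributes, tb$related)
}

#' Write a fixture terminology to a directory of TSV tables
#'
#' @param backend an `rx_fixture_backend`.
#' @param dir output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_terminology <- function(backend, dir) {
  stopifnot(inherits(backend, "rx_fixture_backend"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  for (nm in names(terminology_files)) {
    readr::write_tsv(backend[[nm]], file.path(dir, terminology_files[[nm]]),
                     progress = FALSE)
  }
  invisible(dir)
}
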