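#' Worked-example fixture: one detected selection error and the mismatch taxonomy
#'
#' A hand-built terminology snapshot plus eight record pairs encoding the
#' prototypical cases the double-check must handle, one per outcome:
#'
#' * a detected selection error — a diltiazem extended-release capsule
#'   prescribed (NDC 00093-5117-98, SCD 830845) but a Protonix 40 mg
#'   delayed-release tablet dispensed (NDC 00008-0841-81, SBD 284400,
#'   resolving to SCD 314200): different ingredients, a clinically
#'   significant mismatch;
#' * a clean match (Bystolic 2.5 mg oral tablet on both sides, 751620);
#' * one mismatch per taxonomy category: different ingredient
#'   (venlafaxine 313585 vs levothyroxine 966225), different strength
#'   (pancrelipase capsules 861700 vs 1595476 differing only in enzyme
#'   unit strengths), different pack quantity (risedronate 35 mg tablet
#'   12-pack 905100 vs 4-pack 905092), different dose form (testosterone
#'   cypionate 200 mg/mL injectable solution 835840 vs 1 mL injection
#'   2047882), a proprietary concept pair outside the curated scope
#'   (1371671 vs 1371861), and a qualitative distinction (24 HR
#'   nifedipine 30 mg ER tablet 198034 vs its osmotic variant 1812011).
#'
#' All NDCs other than the two real codes above are synthetic, drawn from
#' the reserved labeler `99999`.
#'
#' @return A list with `backend` (an `rx_fixture_backend`), `pairs` (a
#'   record-pair tibble with an extra `source` column: `"example"` for
#'   the detected-error pair, `"taxonomy"` for the seven taxonomy
#'   pairs), and `expected` (per pair: `pair_id`, `expected_status`,
#'   `expected_category`).
#' @export
inpaper_fixture <- function() {
  concepts <- tibble::tribble(
    ~rxcui, ~tty, ~name, ~status, ~remapped_to, ~curated,
    "830845", "SCD", "24 HR diltiazem hydrochloride 180 mg extended release oral capsule", "active", NA, TRUE,
    "314200", "SCD", "pantoprazole 40 mg delayed release oral tablet", "active", NA, TRUE,
    "284400", "SBD", "Protonix 40 mg delayed release oral tablet", "active", NA, TRUE,
    "751620", "SCD", "Bystolic 2.5 mg oral tablet", "active", NA, TRUE,
    "313585", "SCD", "24 HR venlafaxine 75 mg extended release oral capsule", "active", NA, TRUE,
    "966225", "SCD", "Levothyroxine sodium 0.15 mg oral tablet", "active", NA, TRUE,
    "861700", "SCD", "Amylases 82000 UNT/endopeptidases 51000 UNT/lipase 15000 UNT delayed release oral capsule", "active", NA, TRUE,
    "1595476", "SCD", "Amylases 84000 UNT/endopeptidases 63000 UNT/lipase 20000 UNT delayed release oral capsule", "active", NA, TRUE,
    "905100", "GPCK", "12 (risedronate sodium 35 mg oral tablet) pack", "active", NA, TRUE,
    "905092", "GPCK", "4 (risedronate sodium 35 mg oral tablet) pack", "active", NA, TRUE,
    "904914", "SCD", "risedronate sodium 35 mg oral tablet", "active", NA, TRUE,
    "835840", "SCD", "testosterone cypionate 200 mg/mL injectable solution", "active", NA, TRUE,
    "2047882", "SCD", "1 mL testosterone cypionate 200 mg/mL injection", "active", NA, TRUE,
    "1371671", "OTHER", "Proprietary", "active", NA, FALSE,
    "1371861", "OTHER", "Proprietary", "active", NA, FALSE,
    "198034", "SCD", "24 HR nifedipine 30 mg extended release oral tablet", "active", NA, TRUE,
    "1812011", "SCD", "Osmotic 24 HR nifedipine 30 mg extended release oral tablet", "active", NA, TRUE
  )

  attr_row <- function(rxcui, ingredient, value, unit, form, pack = NA,
                       quals = "") {
    tibble::tibble(rxcui = rxcui, ingredient = ingredient,
                   strength_value = value, strength_unit = unit,
                   dose_form = form, pack_quantity = as.integer(pack),
                   qualifiers = quals)
  }
  panc <- function(rxcui, a, e, l) dplyr::bind_rows(
    attr_row(rxcui, "amylases", a, "UNT", "delayed release oral capsule"),
    attr_row(rxcui, "endopeptidases", e, "UNT",
             "delayed release oral capsule"),
    attr_row(rxcui, "lipase", l, "UNT", "delayed release oral capsule"))
  scd_attributes <- dplyr::bind_rows(
    attr_row("830845", "diltiazem hydrochloride", 180, "mg",
             "extended release oral capsule", quals = "24 hr"),
    attr_row("314200", "pantoprazole", 40, "mg",
             "delayed release oral tablet"),
    attr_row("751620", "nebivolol", 2.5, "mg", "oral tablet"),
    attr_row("313585", "venlafaxine", 75, "mg",
             "extended release oral capsule", quals = "24 hr"),
    attr_row("966225", "levothyroxine sodium", 0.15, "mg", "oral tablet"),
    panc("861700", 82000, 51000, 15000),
    panc("1595476", 84000, 63000, 20000),
    attr_row("905100", "risedronate sodium", 35, "mg", "oral tablet",
             pack = 12),
    attr_row("905092", "risedronate sodium", 35, "mg", "oral tablet",
             pack = 4),
    attr_row("904914", "risedronate sodium", 35, "mg", "oral tablet"),
    attr_row("835840", "testosterone cypionate", 200, "mg/mL",
             "injectable solution"),
    attr_row("2047882", "testosterone cypionate", 200, "mg/mL",
             "injection"),
    attr_row("198034", "nifedipine", 30, "mg",
             "extended release oral tablet", quals = "24 hr"),
    attr_row("1812011", "nifedipine", 30, "mg",
             "extended release oral tablet", quals = "24 hr;osmotic")
  )

  related <- tibble::tribble(
    ~rxcui, ~related_rxcui, ~relation,
    "284400", "314200", "tradename_of",
    "905100", "904914", "contains",
    "905092", "904914", "contains"
  )

  syn <- function(prod, pkg) sprintf("99999%04d%02d", prod, pkg)
  ndc_map <- tibble::tribble(
    ~ndc11, ~rxcui, ~ndc_status,
    "00093511798", "830845", "active",   # diltiazem ER capsule
    "00008084181", "284400", "active",   # Protonix (branded pantoprazole)
    syn(1, 1), "751620", "active",
    syn(1, 2), "751620", "active",
    syn(2, 1), "313585", "active",
    syn(3, 1), "966225", "active",
    syn(4, 1), "861700", "active",
    syn(5, 1), "1595476", "active",
    syn(6, 1), "905100", "active",
    syn(7, 1), "905092", "active",
    syn(8, 1), "835840", "active",
    syn(9, 1), "2047882", "active",
    syn(10, 1), "1371671", "active",
    syn(11, 1), "1371861", "active",
    syn(12, 1), "198034", "active",
    syn(13, 1), "1812011", "active"
  )

  backend <- terminology_fixture(concepts, ndc_map, scd_attributes, related)

  nm <- function(id) concepts$name[concepts$rxcui == id]
  pair <- function(pid, rx_id, rx_ndc, disp_id, disp_ndc, source) {
    tibble::tibble(pair_id = pid, rx_name = nm(rx_id), rx_ndc = rx_ndc,
                   disp_name = nm(disp_id), disp_ndc = disp_ndc,
                   prescriber_id = NA_character_, source = source)
  }
  pairs <- dplyr::bind_rows(
    pair("example_error", "830845", "00093-5117-98",
         "284400", "00008-0841-81", "example"),
    pair("same_medication", "751620", syn(1, 1), "751620", syn(1, 2),
         "taxonomy"),
    pair("diff_ingredient", "313585", syn(2, 1), "966225", syn(3, 1),
         "taxonomy"),
    pair("diff_strength", "861700", syn(4, 1), "1595476", syn(5, 1),
         "taxonomy"),
    pair("diff_pack_quantity", "905100", syn(6, 1), "905092", syn(7, 1),
         "taxonomy"),
    pair("diff_form", "835840", syn(8, 1), "2047882", syn(9, 1),
         "taxonomy"),
    pair("outside_terminology", "1371671", syn(10, 1), "1371861",
         syn(11, 1), "taxonomy"),
    pair("other_qualitative", "198034", syn(12, 1), "1812011", syn(13, 1),
         "taxonomy")
  )

  expected <- tibble::tribble(
    ~pair_id, ~expected_status, ~expected_category,
    "example_error", "MISMATCH", "DIFFERENT_INGREDIENT",
    "same_medication", "MATCH", NA_character_,
    "diff_ingredient", "MISMATCH", "DIFFERENT_INGREDIENT",
    "diff_strength", "MISMATCH", "DIFFERENT_STRENGTH",
    "diff_pack_quantity", "MISMATCH", "DIFFERENT_PACK_QUANTITY",
    "diff_form", "MISMATCH", "DIFFERENT_FORM",
    "outside_terminology", "MISMATCH", "OUTSIDE_RXNORM",
    "other_qualitative", "MISMATCH", "OTHER_QUALITATIVE"
  )

  list(backend = backend, pairs = pairs, expected = expected)
}
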