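# Shared fixtures built in code.

# A small hand-built terminology: two single-ingredient SCDs of the same
# drug at two strengths, a two-ingredient SCD, an SBD, a pack in two
# sizes, an uncurated concept, an unknown NDC, and an obsolete NDC whose
# retired concept is remapped to an active one. Qualifier-free and free
# of compound units so the live-API property encoding can express every
# attribute (used by the backend-equivalence tests).
tiny_backend <- function() {
  concepts <- tibble::tribble(
    ~rxcui, ~tty, ~name, ~status, ~remapped_to, ~curated,
    "100", "SCD", "drugA 10 mg oral tablet", "active", NA, TRUE,
    "101", "SCD", "drugA 20 mg oral tablet", "active", NA, TRUE,
    "102", "SCD", "drugB 10 mg oral tablet", "active", NA, TRUE,
    "103", "SCD", "drugA 10 mg oral solution", "active", NA, TRUE,
    "110", "SCD", "comboA 100 UNT comboB 50 UNT oral capsule", "active", NA, TRUE,
    "200", "SBD", "BrandA 10 mg oral tablet", "active", NA, TRUE,
    "300", "GPCK", "12 (drugA 10 mg oral tablet) pack", "active", NA, TRUE,
    "301", "GPCK", "4 (drugA 10 mg oral tablet) pack", "active", NA, TRUE,
    "400", "OTHER", "Proprietary thing", "active", NA, FALSE,
    "500", "SCD", "drugA 10 mg oral tablet (retired)", "remapped", "100", TRUE
  )
  attr_row <- function(rxcui, ing, val, unit, form, pack = NA) {
    tibble::tibble(rxcui = rxcui, ingredient = ing, strength_value = val,
                   strength_unit = unit, dose_form = form,
                   pack_quantity = as.integer(pack), qualifiers = "")
  }
  scd_attributes <- dplyr::bind_rows(
    attr_row("100", "drugA", 10, "mg", "oral tablet"),
    attr_row("101", "drugA", 20, "mg", "oral tablet"),
    attr_row("102", "drugB", 10, "mg", "oral tablet"),
    attr_row("103", "drugA", 10, "mg", "oral solution"),
    attr_row("110", "comboA", 100, "UNT", "oral capsule"),
    attr_row("110", "comboB", 50, "UNT", "oral capsule"),
    attr_row("300", "drugA", 10, "mg", "oral tablet", pack = 12),
    attr_row("301", "drugA", 10, "mg", "oral tablet", pack = 4)
  )
  related <- tibble::tribble(
    ~rxcui, ~related_rxcui, ~relation,
    "200", "100", "tradename_of",
    "300", "100", "contains",
    "301", "100", "contains"
  )
  ndc_map <- tibble::tribble(
    ~ndc11, ~rxcui, ~ndc_status,
    "11111000101", "100", "active",
    "11111000102", "100", "active",
    "11111000201", "101", "active",
    "11111000301", "102", "active",
    "11111000401", "103", "active",
    "11111000501", "110", "active",
    "11111000601", "200", "active",
    "11111000701", "300", "active",
    "11111000801", "301", "active",
    "11111000901", "400", "active",
    "11111001001", "500", "obsolete"
  )
  terminology_fixture(concepts, ndc_map, scd_attributes, related)
}

# Transport emulating the RxNorm REST endpoints from a fixture snapshot:
# the "recorded live service" for backend-equivalence tests.
mock_transport <- function(fx) {
  js <- function(x) jsonlite::toJSON(x, auto_unbox = TRUE, null = "null")
  concept_json <- function(id) {
    row <- fx$concepts[fx$concepts$rxcui == id, ]
    list(rxcui = row$rxcui, name = row$name, tty = row$tty,
         suppress = if (row$curated) "N" else "Y")
  }
  group <- function(ids) {
    if (!length(ids)) return(list())
    list(list(conceptProperties = lapply(ids, concept_json)))
  }
  function(url) {
    path <- sub("^.*?/REST/", "", url)
    if (grepl("^ndcstatus", path)) {
      ndc <- sub(".*ndc=", "", path)
      concept <- ndc_to_concept(fx, ndc)  # live service resolves history
      if (is.null(concept)) {
        return(js(list(ndcStatus = list(status = "UNKNOWN"))))
      }
      i <- match(ndc, fx$ndc_map$ndc11)
      return(js(list(ndcStatus = list(
        status = toupper(fx$ndc_map$ndc_status[i]),
        rxcui = concept$rxcui))))
    }
    m <- regmatches(path, regexec("^rxcui/([0-9]+)/properties", path))[[1]]
    if (length(m)) {
      return(js(list(properties = concept_json(m[2]))))
    }
    m <- regmatches(path,
                    regexec("^rxcui/([0-9]+)/related\\.json\\?tty=(\\w+)",
                            path))[[1]]
    if (length(m)) {
      id <- m[2]; tty <- m[3]
      if (tty %in% c("SCD", "GPCK")) {
        rel <- fx$related$related_rxcui[fx$related$rxcui == id]
        rel_tty <- fx$concepts$tty[match(rel, fx$concepts$rxcui)]
        ids <- rel[rel_tty == tty]
        # pack "contains" rows are components, not generic counterparts:
        # only branded concepts expose SCD/GPCK relations here
        own <- fx$concepts$tty[match(id, fx$concepts$rxcui)]
        if (!own %in% c("SBD", "BPCK")) ids <- character()
        return(js(list(relatedGroup = list(conceptGroup = group(ids)))))
      }
      att <- fx$scd_attributes[fx$scd_attributes$rxcui == id, ]
      if (tty == "IN") {
        ings <- sort(unique(att$ingredient))
        grp <- list(list(conceptProperties = lapply(ings, function(nm)
          list(rxcui = paste0("IN", nm), name = nm, tty = "IN",
               suppress = "N"))))
        return(js(list(relatedGroup = list(
          conceptGroup = if (length(ings)) grp else list()))))
      }
      if (tty == "DF") {
        dfs <- unique(att$dose_form)
        grp <- list(list(conceptProperties = lapply(dfs, function(nm)
          list(rxcui = paste0("DF", nm), name = nm, tty = "DF",
               suppress = "N"))))
        return(js(list(relatedGroup = list(
          conceptGroup = if (length(dfs)) grp else list()))))
      }
      return(js(list(relatedGroup = list(conceptGroup = list()))))
    }
    m <- regmatches(path, regexec("^rxcui/([0-9]+)/allProperties", path))[[1]]
    if (length(m)) {
      att <- fx$scd_attributes[fx$scd_attributes$rxcui == m[2], ]
      att <- att[order(att$ingredient), ]
      pc <- list()
      if (nrow(att) && any(!is.na(att$strength_value))) {
        strength <- paste(sprintf("%g %s", att$strength_value,
                                  att$strength_unit), collapse = " / ")
        pc <- list(list(propName = "AVAILABLE_STRENGTH",
                        propValue = strength))
      }
      return(js(list(propConceptGroup = list(propConcept = pc))))
    }
    stop("mock transport: unhandled url ", url)
  }
}

# brute-force mismatch classifier used as an independent oracle: tests
# every attribute difference and applies the documented precedence
brute_force_classify <- function(attrs_rx, attrs_disp) {
  ar <- if (inherits(attrs_rx, "scd_attributes")) list(attrs_rx) else attrs_rx
  ad <- if (inherits(attrs_disp, "scd_attributes")) list(attrs_disp) else
    attrs_disp
  if (any(!vapply(c(ar, ad), function(a) isTRUE(a$curated), logical(1))))
    return("OUTSIDE_RXNORM")
  pick <- function(lst) {
    ids <- vapply(lst, function(a) a$scd_rxcui, character(1))
    lst[[order(ids)[1]]]
  }
  a <- pick(ar); b <- pick(ad)
  diffs <- character()
  if (!setequal(a$ingredients, b$ingredients))
    diffs <- c(diffs, "DIFFERENT_INGREDIENT")
  same_strength <- TRUE
  for (k in union(names(a$strengths), names(b$strengths))) {
    sa <- a$strengths[[k]]; sb <- b$strengths[[k]]
    if (is.null(sa) || is.null(sb) || sa$value != sb$value ||
        tolower(trimws(sa$unit)) != tolower(trimws(sb$unit)))
      same_strength <- FALSE
  }
  if (!same_strength) diffs <- c(diffs, "DIFFERENT_STRENGTH")
  qa <- a$pack_quantity; qb <- b$pack_quantity
  if (xor(is.na(qa), is.na(qb)) || (!is.na(qa) && !is.na(qb) && qa != qb))
    diffs <- c(diffs, "DIFFERENT_PACK_QUANTITY")
  if (!identical(a$dose_form, b$dose_form))
    diffs <- c(diffs, "DIFFERENT_FORM")
  precedence <- c("DIFFERENT_INGREDIENT", "DIFFERENT_STRENGTH",
                  "DIFFERENT_PACK_QUANTITY", "DIFFERENT_FORM")
  hit <- precedence[precedence %in% diffs]
  if (length(hit)) hit[1] else "OTHER_QUALITATIVE"
}

# random scd_attributes over a small attribute universe
random_attrs <- function(id) {
  ings <- sort(sample(c("a", "b", "c"), sample(1:2, 1)))
  strengths <- lapply(ings, function(i)
    list(value = sample(c(10, 20), 1), unit = "mg"))
  names(strengths) <- ings
  rxmatch:::new_scd_attributes(
    scd_rxcui = as.character(id),
    curated = stats::runif(1) > 0.1,
    ingredients = ings,
    strengths = strengths,
    dose_form = sample(c("oral tablet", "oral solution"), 1),
    pack_quantity = sample(c(NA_integer_, 4L, 12L), 1),
    qualifiers = if (stats::runif(1) < 0.3) "sugar-free" else character()
  )
}
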