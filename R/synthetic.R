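#' Configuration for the synthetic terminology and record-pair generator
#'
#' The generator emulates the statistical structure of a mail-order
#' pharmacy feed checked against a curated drug terminology: a formulary
#' of clinical drugs (ingredient x strength x dose form), branded
#' counterparts, pack concepts in several counts, qualifier twins
#' (e.g. sugar-free variants), a couple of concepts outside the curated
#' scope, an obsolete NDC remapped to an active concept, and a stream of
#' e-prescription/dispensing pairs in which each mismatch category occurs
#' at a configurable rate.
#'
#' Default rates are the frequencies observed in a 527,009-pair
#' mail-order stream: per-pair probabilities of roughly 5.7e-6 (different
#' ingredient), 1.9e-6 (strength), 5.4e-4 (pack quantity), 1.3e-4 (dose
#' form), 7.6e-5 (outside terminology) and 3.0e-4 (qualitative), with
#' about 1.8% of raw pairs removed at cleaning (split here between
#' signal-worded and missing-NDC rows) and no mapping corruption. The
#' remainder of the probability mass is true matches.
#'
#' @param n_ingredients,n_strength_levels,n_forms formulary grid: every
#'   ingredient is generated at every strength level in every dose form.
#' @param n_brands number of branded (SBD) counterparts.
#' @param n_packs number of pack families; each family is one tablet
#'   concept wrapped in two pack sizes (4 and 12 units).
#' @param ndcs_per_concept NDCs mapped to each concept (the one-to-many
#'   concept-to-NDC relation).
#' @param rate_missing_ndc,rate_signal_word per-pair probability of a
#'   blank NDC / an injected signal word (both removed at cleaning).
#' @param rate_ingredient,rate_strength,rate_pack_quantity,rate_form,rate_outside,rate_other
#'   per-pair probability of each mismatch category.
#' @param rate_mapping_corruption per-pair probability of a truly
#'   different drug whose NDC is (corruptly) mapped to the prescribed
#'   concept — the only source of false negatives.
#' @param n_pairs number of record pairs to draw.
#' @param seed RNG seed; the generator is fully deterministic given the
#'   config.
#' @return A validated `generator_config` list.
#' @export
generator_config <- function(n_ingredients = 50L,
                             n_strength_levels = 3L,
                             n_forms = 2L,
                             n_brands = 10L,
                             n_packs = 4L,
                             ndcs_per_concept = 2L,
                             rate_missing_ndc = 0.008,
                             rate_signal_word = 0.010,
                             rate_ingredient = 3 / 527009,
                             rate_strength = 1 / 527009,
                             rate_pack_quantity = 285 / 527009,
                             rate_form = 67 / 527009,
                             rate_outside = 40 / 527009,
                             rate_other = 159 / 527009,
                             rate_mapping_corruption = 0,
                             n_pairs = 10000L,
                             seed = 1L) {
  cfg <- list(
    n_ingredients = as.integer(n_ingredients),
    n_strength_levels = as.integer(n_strength_levels),
    n_forms = as.integer(n_forms),
    n_brands = as.integer(n_brands),
    n_packs = as.integer(n_packs),
    ndcs_per_concept = as.integer(ndcs_per_concept),
    rates = c(missing_ndc = rate_missing_ndc,
              signal_word = rate_signal_word,
              ingredient = rate_ingredient,
              strength = rate_strength,
              pack_quantity = rate_pack_quantity,
              form = rate_form,
              outside = rate_outside,
              other = rate_other,
              corruption = rate_mapping_corruption),
    n_pairs = as.integer(n_pairs),
    seed = as.integer(seed)
  )
  counts <- unlist(cfg[c("n_ingredients", "n_strength_levels", "n_forms",
                         "n_brands", "n_packs", "ndcs_per_concept",
                         "n_pairs")])
  if (any(is.na(counts)) || any(counts < 0) || cfg$ndcs_per_concept < 1L ||
      cfg$n_ingredients < 1L || cfg$n_strength_levels < 1L ||
      cfg$n_forms < 1L)
    rx_abort("rxmatch_config_error", "invalid generator counts")
  if (any(cfg$rates < 0) || any(cfg$rates > 1))
    rx_abort("rxmatch_config_error", "rates must lie in [0, 1]")
  if (sum(cfg$rates) > 1)
    rx_abort("rxmatch_config_error",
             sprintf("rates sum to %.3f > 1", sum(cfg$rates)))
  structure(cfg, class = "generator_config")
}

synthetic_forms <- c("oral tablet", "oral capsule", "oral solution",
                     "topical cream", "injectable solution")
SYNTHETIC_LABELER <- "99999"

#' Build a deterministic fixture terminology from a generator config
#'
#' Produces an [terminology_fixture()] backend whose tables contain, for
#' the configured grid: one SCD per ingredient x strength level x dose
#' form; a sugar-free qualifier twin per ingredient; `n_brands` SBDs
#' linked to their SCDs; `n_packs` pack families (two GPCK sizes each,
#' linked to their component tablet); two uncurated concepts; one retired
#' concept remapped to an active SCD, reachable through an obsolete NDC;
#' and `ndcs_per_concept` NDCs per concept under the reserved synthetic
#' labeler `99999`. When `rate_mapping_corruption > 0`, one additional
#' corrupt NDC per ingredient is mapped to that ingredient's base SCD
#' while truly belonging to a different drug (recorded in the backend's
#' `meta$corrupt` table — the ground truth the pipeline cannot see).
#'
#' The output is a pure function of the config: the same config yields
#' byte-identical tables.
#'
#' @param config a [generator_config()].
#' @return An `rx_fixture_backend` with a `meta` element describing the
#'   generated structure (used by [generate_record_pairs()]).
#' @export
build_fixture_terminology <- function(config) {
  stopifnot(inherits(config, "generator_config"))
  next_id <- local({ id <- 900000L; function() { id <<- id + 1L; id } },
                   envir = new.env())
  new_rxcui <- function() as.character(next_id())

  forms <- rep_len(synthetic_forms, config$n_forms)
  ing_names <- sprintf("ing%03d", seq_len(config$n_ingredients))

  concepts <- list(); attrs <- list(); related <- list()
  add_concept <- function(rxcui, tty, name, status = "active",
                          remapped_to = NA_character_, curated = TRUE) {
    concepts[[length(concepts) + 1L]] <<- tibble::tibble(
      rxcui = rxcui, tty = tty, name = name, status = status,
      remapped_to = remapped_to, curated = curated)
  }
  add_attrs <- function(rxcui, ingredients, values, unit, form,
                        pack_quantity = NA_integer_, qualifiers = "") {
    attrs[[length(attrs) + 1L]] <<- tibble::tibble(
      rxcui = rxcui, ingredient = ingredients, strength_value = values,
      strength_unit = unit, dose_form = form,
      pack_quantity = pack_quantity, qualifiers = qualifiers)
  }
  add_related <- function(rxcui, related_rxcui, relation) {
    related[[length(related) + 1L]] <<- tibble::tibble(
      rxcui = rxcui, related_rxcui = related_rxcui, relation = relation)
  }

  # SCD grid: ingredient x strength level x dose form
  grid <- expand.grid(ing = seq_len(config$n_ingredients),
                      level = seq_len(config$n_strength_levels),
                      form = seq_len(config$n_forms))
  grid <- grid[order(grid$ing, grid$level, grid$form), ]
  grid$rxcui <- vapply(seq_len(nrow(grid)), function(i) new_rxcui(),
                       character(1))
  grid$kind <- "plain"
  grid$pack_quantity <- NA_integer_
  grid_names <- sprintf("%s %d mg %s", ing_names[grid$ing], 10 * grid$level,
                        forms[grid$form])
  concepts[[1L]] <- tibble::tibble(
    rxcui = grid$rxcui, tty = "SCD", name = grid_names, status = "active",
    remapped_to = NA_character_, curated = TRUE)
  attrs[[1L]] <- tibble::tibble(
    rxcui = grid$rxcui, ingredient = ing_names[grid$ing],
    strength_value = 10 * grid$level, strength_unit = "mg",
    dose_form = forms[grid$form], pack_quantity = NA_integer_,
    qualifiers = "")
  base_scd <- function(ing) {
    grid$rxcui[grid$ing == ing & grid$level == 1L & grid$form == 1L &
                 grid$kind == "plain"][1L]
  }

  # qualifier twins: sugar-free variant of each ingredient's base concept
  twins <- tibble::tibble(ing = seq_len(config$n_ingredients),
                          rxcui = NA_character_, twin_of = NA_character_)
  for (i in seq_len(config$n_ingredients)) {
    id <- new_rxcui()
    twins$rxcui[i] <- id
    twins$twin_of[i] <- base_scd(i)
    add_concept(id, "SCD",
                sprintf("sugar-free %s 10 mg %s", ing_names[i], forms[1L]))
    add_attrs(id, ing_names[i], 10, "mg", forms[1L],
              qualifiers = "sugar-free")
  }

  # pack families: one component tablet wrapped in two pack sizes
  pack_sizes <- c(4L, 12L)
  packs <- NULL
  if (config$n_packs > 0L) {
    packs <- tibble::tibble(
      family = rep(seq_len(config$n_packs), each = length(pack_sizes)),
      size = rep(pack_sizes, config$n_packs),
      rxcui = NA_character_)
    for (k in seq_len(nrow(packs))) {
      fam_ing <- ((packs$family[k] - 1L) %% config$n_ingredients) + 1L
      comp <- base_scd(fam_ing)
      id <- new_rxcui()
      packs$rxcui[k] <- id
      add_concept(id, "GPCK",
                  sprintf("%d (%s 10 mg %s) pack", packs$size[k],
                          ing_names[fam_ing], forms[1L]))
      add_attrs(id, ing_names[fam_ing], 10, "mg", forms[1L],
                pack_quantity = packs$size[k])
      add_related(id, comp, "contains")
    }
  }

  # branded counterparts of the first n_brands grid concepts
  brands <- NULL
  if (config$n_brands > 0L) {
    pick <- head(seq_len(nrow(grid)), config$n_brands)
    brands <- tibble::tibble(scd = grid$rxcui[pick], rxcui = NA_character_)
    for (b in seq_along(pick)) {
      id <- new_rxcui()
      brands$rxcui[b] <- id
      g <- grid[pick[b], ]
      add_concept(id, "SBD",
                  sprintf("Brand%02d %d mg %s", b, 10 * g$level,
                          forms[g$form]))
      add_related(id, g$rxcui, "tradename_of")
    }
  }

  # concepts outside the curated scope
  uncurated <- c(new_rxcui(), new_rxcui())
  add_concept(uncurated[1L], "OTHER", "Proprietary compound A",
              curated = FALSE)
  add_concept(uncurated[2L], "OTHER", "Proprietary compound B",
              curated = FALSE)

  # retired concept remapped to an active one, reached via an obsolete NDC
  retired <- new_rxcui()
  add_concept(retired, "SCD", sprintf("%s 10 mg %s (retired)",
                                      ing_names[1L], forms[1L]),
              status = "remapped", remapped_to = base_scd(1L))

  concepts <- dplyr::bind_rows(concepts)

  # NDC assignment: ndcs_per_concept per concept under the reserved labeler
  all_ids <- concepts$rxcui[concepts$status == "active"]
  if (length(all_ids) >= 8000L)
    rx_abort("rxmatch_config_error",
             "formulary too large for the synthetic NDC numbering scheme")
  ndc_of <- function(concept_index, copy)
    paste0(SYNTHETIC_LABELER, sprintf("%04d", concept_index),
           sprintf("%02d", copy))
  ndc_rows <- list()
  ndc_pool <- list()
  for (j in seq_along(all_ids)) {
    codes <- vapply(seq_len(config$ndcs_per_concept), function(k)
      ndc_of(j, k), character(1))
    ndc_pool[[all_ids[j]]] <- codes
    ndc_rows[[j]] <- tibble::tibble(ndc11 = codes, rxcui = all_ids[j],
                                    ndc_status = "active")
  }
  obsolete_ndc <- paste0(SYNTHETIC_LABELER, "9000", "01")
  ndc_rows[[length(ndc_rows) + 1L]] <- tibble::tibble(
    ndc11 = obsolete_ndc, rxcui = retired, ndc_status = "obsolete")

  corrupt <- tibble::tibble(ndc = character(), mapped_rxcui = character(),
                            true_rxcui = character())
  if (config$rates[["corruption"]] > 0) {
    if (config$n_ingredients < 2L)
      rx_abort("rxmatch_generation_error",
               "mapping corruption needs at least two ingredients")
    for (i in seq_len(config$n_ingredients)) {
      other <- (i %% config$n_ingredients) + 1L
      cndc <- paste0(SYNTHETIC_LABELER, sprintf("8%03d", i), "01")
      corrupt <- dplyr::bind_rows(corrupt, tibble::tibble(
        ndc = cndc, mapped_rxcui = base_scd(i),
        true_rxcui = base_scd(other)))
      ndc_rows[[length(ndc_rows) + 1L]] <- tibble::tibble(
        ndc11 = cndc, rxcui = base_scd(i), ndc_status = "active")
    }
  }

  backend <- terminology_fixture(
    concepts = concepts,
    ndc_map = dplyr::bind_rows(ndc_rows),
    scd_attributes = dplyr::bind_rows(attrs),
    related = if (length(related)) dplyr::bind_rows(related) else
      tibble::tibble(rxcui = character(), related_rxcui = character(),
                     relation = character())
  )
  # prescribable NDC pools: an SCD's own NDCs plus its brand's, flattened
  # for O(1) vectorized draws
  pool_of <- ndc_pool
  if (!is.null(brands)) {
    for (b in seq_len(nrow(brands))) {
      s <- brands$scd[b]
      pool_of[[s]] <- c(pool_of[[s]], ndc_pool[[brands$rxcui[b]]])
    }
  }
  pool_ids <- names(pool_of)
  pool_len <- lengths(pool_of)
  pool_start <- cumsum(c(1L, head(pool_len, -1L)))
  backend$meta <- list(
    config = config, grid = tibble::as_tibble(grid), twins = twins,
    packs = packs, brands = brands, uncurated = uncurated,
    retired = retired, obsolete_ndc = obsolete_ndc,
    corrupt = corrupt, ndc_pool = ndc_pool, forms = forms,
    ing_names = ing_names,
    name_of = setNames(concepts$name, concepts$rxcui),
    pool = list(ids = pool_ids, ndcs = unlist(pool_of, use.names = FALSE),
                start = setNames(pool_start, pool_ids),
                len = setNames(as.integer(pool_len), pool_ids))
  )
  backend
}

#' Generate a record-pair stream with ground truth
#'
#' Draws `n_pairs` e-prescription/dispensing pairs from the fixture
#' terminology. Each pair is assigned a type by one multinomial draw over
#' the configured rates (remainder = true match): the prescribed NDC is
#' drawn from the target concept (or its brand), and the dispensed NDC is
#' swapped for one differing in exactly the drawn category's attribute —
#' a different ingredient, a different strength level, the sibling pack
#' size, a different dose form, the qualifier twin, the second uncurated
#' concept, or (for mapping corruption) a truly different drug whose NDC
#' maps to the prescribed concept. Missing-NDC and signal-word pairs are
#' valid matches degraded at the record level, so they exercise the
#' cleaning funnel.
#'
#' @param backend terminology from [build_fixture_terminology()] (its
#'   `meta` is required).
#' @param config a [generator_config()]; defaults to the config the
#'   terminology was built with.
#' @return A list with `pairs` (a record-pair tibble accepted by
#'   [clean_pairs()]) and `truth` (per pair: `pair_id`,
#'   `intended_status`, `intended_category`, `intended_label`,
#'   `truly_equivalent`).
#' @export
generate_record_pairs <- function(backend, config = backend$meta$config) {
  meta <- backend$meta
  if (is.null(meta))
    rx_abort("rxmatch_config_error",
             "backend lacks generator metadata; build it with build_fixture_terminology()")
  stopifnot(inherits(config, "generator_config"))
  check_generation_feasible(meta, config)

  withr::with_seed(config$seed, draw_pairs(meta, config))
}

# vectorized pair drawing; one multinomial type draw per pair, then one
# attribute swap per non-match type
draw_pairs <- function(meta, config) {
  n <- config$n_pairs
  grid <- meta$grid
  if (n == 0L) {
    empty_pairs <- tibble::tibble(
      pair_id = character(), rx_name = character(), rx_ndc = character(),
      disp_name = character(), disp_ndc = character(),
      prescriber_id = character())
    empty_truth <- tibble::tibble(
      pair_id = character(), intended_status = character(),
      intended_category = character(), intended_label = character(),
      truly_equivalent = logical())
    return(list(pairs = empty_pairs, truth = empty_truth))
  }
  types <- c(names(config$rates), "match")
  probs <- c(unname(config$rates), 1 - sum(config$rates))
  type <- sample(types, n, replace = TRUE, prob = probs)

  gkey <- function(i, l, f) paste(i, l, f, sep = ":")
  gmap <- setNames(grid$rxcui, gkey(grid$ing, grid$level, grid$form))
  bi <- sample.int(nrow(grid), n, replace = TRUE)
  ing <- grid$ing[bi]; level <- grid$level[bi]; form <- grid$form[bi]
  rx_id <- grid$rxcui[bi]
  disp_id <- rx_id
  disp_ndc <- rep(NA_character_, n)

  # swap exactly one attribute per drawn category
  shift <- function(x, m) {
    off <- 1L + floor(stats::runif(length(x)) * (m - 1L))
    ((x - 1L + off) %% m) + 1L
  }
  k <- type == "ingredient"
  if (any(k)) disp_id[k] <- gmap[gkey(shift(ing[k], config$n_ingredients),
                                      level[k], form[k])]
  k <- type == "strength"
  if (any(k)) disp_id[k] <- gmap[gkey(ing[k],
                                      shift(level[k],
                                            config$n_strength_levels),
                                      form[k])]
  k <- type == "form"
  if (any(k)) disp_id[k] <- gmap[gkey(ing[k], level[k],
                                      shift(form[k], config$n_forms))]
  k <- type == "pack_quantity"
  if (any(k)) {
    fams <- unique(meta$packs$family)
    fam <- fams[1L + floor(stats::runif(sum(k)) * length(fams))]
    first <- meta$packs[!duplicated(meta$packs$family), ]
    second <- meta$packs[duplicated(meta$packs$family), ]
    rx_id[k] <- first$rxcui[match(fam, first$family)]
    disp_id[k] <- second$rxcui[match(fam, second$family)]
  }
  k <- type == "outside"
  if (any(k)) { rx_id[k] <- meta$uncurated[1L]
                disp_id[k] <- meta$uncurated[2L] }
  k <- type == "other"
  if (any(k)) { rx_id[k] <- meta$twins$twin_of[ing[k]]
                disp_id[k] <- meta$twins$rxcui[ing[k]] }
  k <- type == "corruption"
  if (any(k)) {
    ci <- 1L + floor(stats::runif(sum(k)) * nrow(meta$corrupt))
    rx_id[k] <- meta$corrupt$mapped_rxcui[ci]
    disp_id[k] <- meta$corrupt$true_rxcui[ci]  # what was truly dispensed
    disp_ndc[k] <- meta$corrupt$ndc[ci]        # maps back to rx_id
  }

  draw_ndc <- function(ids) {
    p <- meta$pool
    j <- match(ids, p$ids)
    p$ndcs[p$start[j] + floor(stats::runif(length(ids)) * p$len[j])]
  }
  rx_ndc <- draw_ndc(rx_id)
  need <- is.na(disp_ndc)
  disp_ndc[need] <- draw_ndc(disp_id[need])

  rx_name <- unname(meta$name_of[rx_id])
  disp_name <- unname(meta$name_of[disp_id])

  cat_map <- c(ingredient = "DIFFERENT_INGREDIENT",
               strength = "DIFFERENT_STRENGTH",
               pack_quantity = "DIFFERENT_PACK_QUANTITY",
               form = "DIFFERENT_FORM",
               outside = "OUTSIDE_RXNORM",
               other = "OTHER_QUALITATIVE")
  is_mismatch <- type %in% names(cat_map)
  category <- rep(NA_character_, n)
  category[is_mismatch] <- unname(cat_map[type[is_mismatch]])
  status <- ifelse(is_mismatch, "MISMATCH", "MATCH")
  label <- ifelse(is_mismatch,
                  ifelse(category %in% c("DIFFERENT_INGREDIENT",
                                         "DIFFERENT_STRENGTH"),
                         "TP", "FP"),
                  ifelse(type == "corruption", "FN", "TN"))
  truly_equivalent <- rep(NA, n)
  truly_equivalent[type == "match" | type == "missing_ndc" |
                     type == "signal_word"] <- TRUE
  truly_equivalent[type == "corruption"] <- FALSE

  k <- type == "missing_ndc"
  if (any(k)) {
    which_side <- stats::runif(sum(k)) < 0.5
    rx_ndc[k][which_side] <- ""
    disp_ndc[k][!which_side] <- ""
    status[k] <- "REMOVED_MISSING_NDC"
    label[k] <- NA_character_
  }
  k <- type == "signal_word"
  if (any(k)) {
    word <- toupper(sample(c("duplicate", "cancel", "wrong", "denied"),
                           sum(k), replace = TRUE))
    disp_name[k] <- paste(disp_name[k], word)
    status[k] <- "REMOVED_SIGNAL_WORD"
    label[k] <- NA_character_
  }

  pid <- sprintf("p%06d", seq_len(n))
  list(
    pairs = tibble::tibble(
      pair_id = pid, rx_name = rx_name, rx_ndc = format_ndc_11(rx_ndc),
      disp_name = disp_name, disp_ndc = format_ndc_11(disp_ndc),
      prescriber_id = sprintf("npi%04d",
                              sample.int(200L, n, replace = TRUE))),
    truth = tibble::tibble(
      pair_id = pid, intended_status = status,
      intended_category = category, intended_label = label,
      truly_equivalent = truly_equivalent)
  )
}

check_generation_feasible <- function(meta, config) {
  r <- config$rates
  say <- function(msg) rx_abort("rxmatch_generation_error", msg)
  if (r[["ingredient"]] > 0 && config$n_ingredients < 2L)
    say("ingredient mismatches need >= 2 ingredients")
  if (r[["strength"]] > 0 && config$n_strength_levels < 2L)
    say("strength mismatches need >= 2 strength levels")
  if (r[["form"]] > 0 && config$n_forms < 2L)
    say("form mismatches need >= 2 dose forms")
  if (r[["pack_quantity"]] > 0 && (is.null(meta$packs) || !nrow(meta$packs)))
    say("pack-quantity mismatches need pack concepts")
  if (r[["corruption"]] > 0 && !nrow(meta$corrupt))
    say("mapping corruption needs corrupt NDC rows in the terminology")
}

format_ndc_11 <- function(x) {
  ifelse(nchar(x) == 11L,
         paste(substr(x, 1, 5), substr(x, 6, 9), substr(x, 10, 11),
               sep = "-"),
         x)
}

#' Write a generated dataset to disk
#'
#' Serializes the terminology tables, the record-pair stream and the
#' ground-truth table produced by [build_fixture_terminology()] and
#' [generate_record_pairs()].
#'
#' @param backend terminology backend with `meta`.
#' @param generated list from [generate_record_pairs()].
#' @param dir output directory.
#' @return `dir`, invisibly.
#' @export
write_synthetic_dataset <- function(backend, generated, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  write_terminology(backend, file.path(dir, "terminology"))
  readr::write_csv(generated$pairs, file.path(dir, "pairs.csv"),
                   progress = FALSE)
  readr::write_tsv(generated$truth, file.path(dir, "ground_truth.tsv"),
                   progress = FALSE)
  if (nrow(backend$meta$corrupt))
    readr::write_tsv(backend$meta$corrupt,
                     file.path(dir, "corrupt_ndcs.tsv"), progress = FALSE)
  invisible(dir)
}
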