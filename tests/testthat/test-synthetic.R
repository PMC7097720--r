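# Synthetic terminology and record-pair generation

test_that("the generator is deterministic for a seed", {
  cfg <- generator_config(n_pairs = 500, seed = 5,
                          rate_mapping_corruption = 0.01)
  be1 <- build_fixture_terminology(cfg)
  be2 <- build_fixture_terminology(cfg)
  for (tbl in c("concepts", "ndc_map", "scd_attributes", "related")) {
    expect_identical(be1[[tbl]], be2[[tbl]])
  }
  gen1 <- generate_record_pairs(be1, cfg)
  gen2 <- generate_record_pairs(be2, cfg)
  expect_identical(gen1, gen2)
  cfg2 <- generator_config(n_pairs = 500, seed = 6,
                           rate_mapping_corruption = 0.01)
  gen3 <- generate_record_pairs(be1, cfg2)
  expect_false(identical(gen1$pairs, gen3$pairs))
  # serialized tables are byte-identical across rebuilds
  d1 <- withr::local_tempdir(); d2 <- withr::local_tempdir()
  write_terminology(be1, d1); write_terminology(be2, d2)
  for (f in list.files(d1)) {
    expect_identical(readLines(file.path(d1, f)),
                     readLines(file.path(d2, f)))
  }
})

test_that("the terminology contains the structures the taxonomy needs", {
  cfg <- generator_config(n_ingredients = 6, n_brands = 3, n_packs = 2,
                          ndcs_per_concept = 3,
                          rate_mapping_corruption = 0.01)
  be <- build_fixture_terminology(cfg)
  expect_gte(sum(be$concepts$tty == "GPCK"), 4)  # 2 families x 2 sizes
  expect_true(any(!be$concepts$curated))
  expect_true(any(be$concepts$status == "remapped"))
  expect_true(any(be$ndc_map$ndc_status == "obsolete"))
  # pack concepts are linked to their component tablet
  packs <- be$concepts$rxcui[be$concepts$tty == "GPCK"]
  expect_true(all(packs %in% be$related$rxcui[be$related$relation ==
                                                "contains"]))
  # the concept-to-NDC relation is one-to-many at the configured width
  n_active <- sum(be$concepts$status == "active")
  expect_equal(nrow(be$ndc_map),
               3 * n_active + 1 + nrow(be$meta$corrupt))
  expect_true(all(startsWith(be$ndc_map$ndc11, "99999")))
  # obsolete NDC reaches the active remap target
  obs <- be$ndc_map$ndc11[be$ndc_map$ndc_status == "obsolete"]
  expect_equal(ndc_to_concept(be, obs)$status, "active")
})

test_that("invalid configurations are rejected", {
  expect_error(generator_config(rate_ingredient = 0.7, rate_other = 0.6),
               class = "rxmatch_config_error")
  expect_error(generator_config(rate_form = -0.1),
               class = "rxmatch_config_error")
  expect_error(generator_config(ndcs_per_concept = 0),
               class = "rxmatch_config_error")
  cfg <- generator_config(n_strength_levels = 1, rate_strength = 0.1)
  be <- build_fixture_terminology(cfg)
  expect_error(generate_record_pairs(be, cfg),
               class = "rxmatch_generation_error")
  cfg2 <- generator_config(n_packs = 0, rate_pack_quantity = 0.1)
  be2 <- build_fixture_terminology(cfg2)
  expect_error(generate_record_pairs(be2, cfg2),
               class = "rxmatch_generation_error")
})

test_that("rate extremes produce pure streams", {
  cfg0 <- generator_config(n_pairs = 300, seed = 9, rate_missing_ndc = 0,
                           rate_signal_word = 0, rate_ingredient = 0,
                           rate_strength = 0, rate_pack_quantity = 0,
                           rate_form = 0, rate_outside = 0,
                           rate_other = 0)
  be <- build_fixture_terminology(cfg0)
  gen0 <- generate_record_pairs(be, cfg0)
  expect_true(all(gen0$truth$intended_status == "MATCH"))
  out0 <- check_pairs(gen0$pairs, be, ground_truth = gen0$truth)
  expect_true(all(out0$status == "MATCH"))

  cfg1 <- generator_config(n_pairs = 300, seed = 9, rate_missing_ndc = 0,
                           rate_signal_word = 0, rate_ingredient = 1,
                           rate_strength = 0, rate_pack_quantity = 0,
                           rate_form = 0, rate_outside = 0,
                           rate_other = 0)
  gen1 <- generate_record_pairs(be, cfg1)
  expect_true(all(gen1$truth$intended_category == "DIFFERENT_INGREDIENT"))
  out1 <- check_pairs(gen1$pairs, be)
  expect_true(all(out1$category == "DIFFERENT_INGREDIENT"))
})

test_that("an empty stream yields empty pair and truth tables", {
  cfg <- generator_config(n_pairs = 0)
  gen <- generate_record_pairs(build_fixture_terminology(cfg), cfg)
  expect_equal(nrow(gen$pairs), 0)
  expect_equal(nrow(gen$truth), 0)
  expect_named(gen$pairs, c("pair_id", "rx_name", "rx_ndc", "disp_name",
                            "disp_ndc", "prescriber_id"))
})

test_that("the pipeline recovers generated categories pair by pair", {
  for (seed in c(101, 202)) {
    cfg <- generator_config(n_pairs = 2000, seed = seed,
                            rate_ingredient = 0.01, rate_strength = 0.005,
                            rate_pack_quantity = 0.02, rate_form = 0.01,
                            rate_outside = 0.005, rate_other = 0.01,
                            rate_mapping_corruption = 0.005)
    be <- build_fixture_terminology(cfg)
    gen <- generate_record_pairs(be, cfg)
    cleaned <- clean_pairs(gen$pairs)
    out <- check_pairs(cleaned$pairs, be, ground_truth = gen$truth)
    merged <- dplyr::inner_join(out, gen$truth, by = "pair_id")
    expect_equal(merged$status, merged$intended_status)
    expect_equal(merged$category, merged$intended_category)
    expect_equal(merged$label, merged$intended_label)
    # cleaning removed exactly the degraded rows
    expect_equal(cleaned$report$n_removed_signal_words +
                   cleaned$report$n_removed_missing_ndc,
                 sum(grepl("^REMOVED", gen$truth$intended_status)))
  }
})

test_that("a generated dataset round-trips through disk", {
  cfg <- generator_config(n_pairs = 200, seed = 77,
                          rate_mapping_corruption = 0.01)
  be <- build_fixture_terminology(cfg)
  gen <- generate_record_pairs(be, cfg)
  dir <- withr::local_tempdir()
  write_synthetic_dataset(be, gen, dir)
  be2 <- read_terminology(file.path(dir, "terminology"))
  pairs2 <- load_pairs(file.path(dir, "pairs.csv"))
  truth2 <- readr::read_tsv(
    file.path(dir, "ground_truth.tsv"),
    col_types = readr::cols(truly_equivalent = "l", .default = "c"))
  out <- check_pairs(clean_pairs(pairs2)$pairs, be2,
                     ground_truth = truth2)
  merged <- dplyr::inner_join(out, truth2, by = "pair_id")
  expect_equal(merged$category, merged$intended_category)
  expect_true(file.exists(file.path(dir, "corrupt_ndcs.tsv")))
})
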