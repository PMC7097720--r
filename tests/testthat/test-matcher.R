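# Matching, mismatch classification, and error-matrix labeling

test_that("set matching distinguishes missing, match and mismatch", {
  expect_equal(match_pair("830845", "314200"), "MISMATCH")
  expect_equal(match_pair("751620", "751620"), "MATCH")
  expect_equal(match_pair(character(), "314200"), "MISSING_RXCUI")
  expect_equal(match_pair("751620", character()), "MISSING_RXCUI")
  # any shared clinical drug counts as a match (brand resolving to several)
  expect_equal(match_pair(c("A", "B"), c("B", "C")), "MATCH")
})

test_that("the cascade names a mismatch by its most harmful difference", {
  mk <- function(id, ings, vals, form = "oral tablet", pack = NA,
                 quals = character(), curated = TRUE, unit = "mg") {
    strengths <- lapply(vals, function(v) list(value = v, unit = unit))
    names(strengths) <- ings
    rxmatch:::new_scd_attributes(id, curated = curated, ingredients = ings,
                                 strengths = strengths, dose_form = form,
                                 pack_quantity = as.integer(pack),
                                 qualifiers = quals)
  }
  a <- mk("1", "drugA", 10)
  expect_equal(classify_mismatch(a, mk("2", "drugB", 10)),
               "DIFFERENT_INGREDIENT")
  expect_equal(classify_mismatch(a, mk("2", "drugA", 20)),
               "DIFFERENT_STRENGTH")
  expect_equal(classify_mismatch(mk("1", "drugA", 10, pack = 12),
                                 mk("2", "drugA", 10, pack = 4)),
               "DIFFERENT_PACK_QUANTITY")
  expect_equal(classify_mismatch(a, mk("2", "drugA", 10,
                                       form = "oral solution")),
               "DIFFERENT_FORM")
  expect_equal(classify_mismatch(a, mk("2", "drugA", 10,
                                       quals = "sugar-free")),
               "OTHER_QUALITATIVE")
  expect_equal(classify_mismatch(a, mk("2", "drugA", 10, curated = FALSE)),
               "OUTSIDE_RXNORM")
  # precedence: a compound difference is named by the most harmful part
  expect_equal(classify_mismatch(a, mk("2", "drugB", 20,
                                       form = "oral solution")),
               "DIFFERENT_INGREDIENT")
  expect_equal(classify_mismatch(a, mk("2", "drugA", 20, pack = 4)),
               "DIFFERENT_STRENGTH")
  # uncurated screens first even when ingredients also differ
  expect_equal(classify_mismatch(mk("1", "drugA", 10, curated = FALSE),
                                 mk("2", "drugB", 10)),
               "OUTSIDE_RXNORM")
  # units compare case-insensitively, with no conversion
  expect_equal(classify_mismatch(mk("1", "drugA", 10, unit = "MG"),
                                 mk("2", "drugA", 10, unit = "mg")),
               "OTHER_QUALITATIVE")
  expect_equal(classify_mismatch(mk("1", "drugA", 1000, unit = "mg"),
                                 mk("2", "drugA", 1, unit = "g")),
               "DIFFERENT_STRENGTH")
})

test_that("cascade output equals a brute-force comparator on random cases", {
  withr::with_seed(21, {
    for (i in 1:300) {
      a <- random_attrs(1)
      b <- random_attrs(2)
      expect_equal(classify_mismatch(a, b), brute_force_classify(a, b))
    }
    # multi-concept sides: smallest-rxcui tie-break on both routes
    for (i in 1:100) {
      a <- lapply(sample(10:99, 2), random_attrs)
      b <- lapply(sample(10:99, 2), random_attrs)
      expect_equal(classify_mismatch(a, b), brute_force_classify(a, b))
    }
  })
})

test_that("labels encode clinical significance", {
  expect_equal(label_outcome("MISMATCH", "DIFFERENT_INGREDIENT"), "TP")
  expect_equal(label_outcome("MISMATCH", "DIFFERENT_STRENGTH"), "TP")
  for (cat in c("DIFFERENT_PACK_QUANTITY", "DIFFERENT_FORM",
                "OUTSIDE_RXNORM", "OTHER_QUALITATIVE")) {
    expect_equal(label_outcome("MISMATCH", cat), "FP")
  }
  expect_equal(label_outcome("MATCH"), "TN")
  expect_equal(label_outcome("MATCH", truly_equivalent = FALSE), "FN")
  expect_true(is.na(label_outcome("MISSING_RXCUI")))
})

test_that("labels partition outcomes: mismatches are TP or FP, matches TN or FN", {
  cfg <- generator_config(n_pairs = 2000, seed = 7,
                          rate_ingredient = 0.02, rate_strength = 0.02,
                          rate_pack_quantity = 0.02, rate_form = 0.02,
                          rate_outside = 0.01, rate_other = 0.02,
                          rate_mapping_corruption = 0.01)
  be <- build_fixture_terminology(cfg)
  gen <- generate_record_pairs(be, cfg)
  cleaned <- clean_pairs(gen$pairs)
  out <- check_pairs(cleaned$pairs, be, ground_truth = gen$truth)
  mism <- out$label[out$status == "MISMATCH"]
  expect_true(all(mism %in% c("TP", "FP")))
  mat <- out$label[out$status == "MATCH"]
  expect_true(all(mat %in% c("TN", "FN")))
  expect_true(all(is.na(out$label[out$status == "MISSING_RXCUI"])))
})

test_that("false negatives arise only from injected mapping corruption", {
  cfg <- generator_config(n_pairs = 3000, seed = 19,
                          rate_mapping_corruption = 0.01)
  be <- build_fixture_terminology(cfg)
  gen <- generate_record_pairs(be, cfg)
  cleaned <- clean_pairs(gen$pairs)
  out <- check_pairs(cleaned$pairs, be, ground_truth = gen$truth)
  injected <- gen$truth$pair_id[!is.na(gen$truth$intended_label) &
                                  gen$truth$intended_label == "FN"]
  detected <- out$pair_id[!is.na(out$label) & out$label == "FN"]
  expect_setequal(detected, injected)
  expect_gt(length(injected), 0)
  # without ground truth the same run shows no false negatives
  out2 <- check_pairs(cleaned$pairs, be)
  expect_equal(sum(out2$label == "FN", na.rm = TRUE), 0)
})

test_that("with a defect-free terminology, sensitivity is exactly 1", {
  cfg <- generator_config(n_pairs = 2000, seed = 3,
                          rate_ingredient = 0.02, rate_strength = 0.02)
  be <- build_fixture_terminology(cfg)
  gen <- generate_record_pairs(be, cfg)
  rep <- run_check(gen$pairs, be, ground_truth = gen$truth)
  expect_equal(rep$matrix_total[["fn"]], 0L)
  expect_equal(rep$metrics$sensitivity[rep$metrics$mode == "total"], 1)
})
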