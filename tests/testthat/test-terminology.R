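# Terminology backends: NDC -> concept -> SCD resolution and attributes

test_that("NDCs resolve to concepts; unknown NDCs are a data outcome", {
  fx <- inpaper_fixture()$backend
  concept <- ndc_to_concept(fx, "00008084181")
  expect_equal(concept$rxcui, "284400")
  expect_equal(concept$tty, "SBD")
  expect_null(ndc_to_concept(fx, "99999999999"))
})

test_that("obsolete NDCs are remapped to the current active concept", {
  fx <- tiny_backend()
  concept <- ndc_to_concept(fx, "11111001001")  # retired 500 -> active 100
  expect_equal(concept$rxcui, "100")
  expect_equal(concept$status, "active")
})

test_that("concepts resolve to clinical-drug identifiers by term type", {
  fx <- inpaper_fixture()$backend
  expect_equal(resolve_to_scds(fx, "284400"), "314200")  # brand -> generic
  expect_equal(resolve_to_scds(fx, "314200"), "314200")  # SCD -> itself
  # generic packs are clinical-drug-level: pack identity is preserved so
  # that two counts of the same tablet remain distinguishable
  expect_equal(resolve_to_scds(fx, "905100"), "905100")
  expect_equal(resolve_to_scds(fx, "905092"), "905092")
  # uncurated concepts resolve to themselves, flagged downstream
  expect_equal(resolve_to_scds(fx, "1371671"), "1371671")
  expect_error(resolve_to_scds(fx, "000000"),
               class = "rxmatch_unknown_concept")
})

test_that("a branded concept without a related generic is a resolution error", {
  fx <- terminology_fixture(
    concepts = tibble::tibble(rxcui = "1", tty = "SBD", name = "orphan",
                              status = "active",
                              remapped_to = NA_character_, curated = TRUE),
    ndc_map = tibble::tibble(ndc11 = "11111000101", rxcui = "1",
                             ndc_status = "active"),
    scd_attributes = tibble::tibble(rxcui = character(),
                                    ingredient = character(),
                                    strength_value = numeric(),
                                    strength_unit = character(),
                                    dose_form = character(),
                                    pack_quantity = integer(),
                                    qualifiers = character()),
    related = tibble::tibble(rxcui = character(),
                             related_rxcui = character(),
                             relation = character()))
  expect_error(resolve_to_scds(fx, "1"), class = "rxmatch_resolution_error")
})

test_that("attributes carry ingredients, strengths, form, pack and flags", {
  fx <- inpaper_fixture()$backend
  pack <- get_scd_attributes(fx, "905100")
  expect_equal(pack$pack_quantity, 12L)
  expect_equal(pack$ingredients, "risedronate sodium")
  panc <- get_scd_attributes(fx, "861700")
  expect_setequal(panc$ingredients, c("amylases", "endopeptidases",
                                      "lipase"))
  expect_equal(panc$strengths$amylases, list(value = 82000, unit = "unt"))
  stub <- get_scd_attributes(fx, "1371671")
  expect_false(stub$curated)
  expect_length(stub$ingredients, 0)
  expect_error(get_scd_attributes(fx, "000000"),
               class = "rxmatch_unknown_concept")
  expect_error(get_scd_attributes(tiny_backend(), "500"),
               class = "rxmatch_attribute_unavailable")
})

test_that("snapshot integrity is enforced at construction", {
  fx <- tiny_backend()
  dup <- fx$ndc_map
  dup <- rbind(dup, tibble::tibble(ndc11 = "11111000101", rxcui = "101",
                                   ndc_status = "active"))
  expect_error(terminology_fixture(fx$concepts, dup, fx$scd_attributes,
                                   fx$related),
               class = "rxmatch_format_error")
  bad <- fx$concepts
  bad$remapped_to[bad$rxcui == "500"] <- NA
  expect_error(terminology_fixture(bad, fx$ndc_map, fx$scd_attributes,
                                   fx$related),
               class = "rxmatch_format_error")
})

test_that("a snapshot survives a TSV round-trip unchanged", {
  fx <- tiny_backend()
  dir <- withr::local_tempdir()
  write_terminology(fx, dir)
  fx2 <- read_terminology(dir)
  for (ndc in fx$ndc_map$ndc11) {
    expect_equal(ndc_to_concept(fx2, ndc), ndc_to_concept(fx, ndc))
  }
  for (id in c("100", "110", "200", "300", "400")) {
    expect_equal(resolve_to_scds(fx2, id), resolve_to_scds(fx, id))
  }
  expect_equal(get_scd_attributes(fx2, "110"), get_scd_attributes(fx, "110"))
  expect_error(read_terminology(withr::local_tempdir()),
               class = "rxmatch_format_error")
})

test_that("fixture and recorded live backends answer identically", {
  fx <- tiny_backend()
  live <- rxnorm_live_backend(base_url = "https://mock.invalid/REST",
                              transport = mock_transport(fx))
  for (ndc in c(fx$ndc_map$ndc11, "99999999999")) {
    expect_equal(ndc_to_concept(live, ndc), ndc_to_concept(fx, ndc),
                 info = ndc)
  }
  for (id in c("100", "101", "102", "103", "110", "200", "300", "301",
               "400")) {
    expect_equal(resolve_to_scds(live, id), resolve_to_scds(fx, id),
                 info = id)
  }
  # attributes are defined for clinical-drug-level and uncurated concepts
  for (id in c("100", "101", "102", "103", "110", "300", "301", "400")) {
    expect_equal(get_scd_attributes(live, id), get_scd_attributes(fx, id),
                 info = id)
  }
})

test_that("live responses are cached persistently and reused", {
  fx <- tiny_backend()
  calls <- 0L
  counting <- function(url) { calls <<- calls + 1L; mock_transport(fx)(url) }
  cache <- withr::local_tempdir()
  live <- rxnorm_live_backend(base_url = "https://mock.invalid/REST",
                              cache_dir = cache, transport = counting,
                              rate_limit = 1e6)
  r1 <- ndc_to_concept(live, "11111000101")
  n1 <- calls
  r2 <- ndc_to_concept(live, "11111000101")
  expect_equal(calls, n1)  # second lookup served from cache
  expect_equal(r1, r2)
  expect_gt(length(list.files(cache)), 0)
  # a fresh handle over the same cache never touches the transport
  live2 <- rxnorm_live_backend(base_url = "https://mock.invalid/REST",
                               cache_dir = cache,
                               transport = function(url)
                                 stop("network touched"))
  expect_equal(ndc_to_concept(live2, "11111000101"), r1)
})

test_that("transport failure after retries signals backend unavailability", {
  attempts <- 0L
  live <- rxnorm_live_backend(
    base_url = "https://mock.invalid/REST",
    transport = function(url) { attempts <<- attempts + 1L; stop("down") },
    retries = 2L, rate_limit = 1e6)
  expect_error(ndc_to_concept(live, "11111000101"),
               class = "rxmatch_backend_unavailable")
  expect_equal(attempts, 2L)
})
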