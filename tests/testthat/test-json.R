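test_that("a duplicated row key is read with both values in order", {
  fix <- cachedFixture(seed = 31, nSamples = 2, nMetabolites = 3)
  doc <- fix$document
  i <- which(doc@sections@keys == "MS_METABOLITE_DATA")
  tab <- doc@sections@values[[i]]
  tab@rows[[1]] <- mapAppend(tab@rows[[1]], "S001", "999.9")
  doc@sections@values[[i]] <- tab
  json <- formatMWTabJSON(doc)
  back <- parseMWTabJSON(json)
  vals <- mapGet(getSection(back, "MS_METABOLITE_DATA")@rows[[1]], "S001")
  expect_length(vals, 2)
  expect_equal(vals[[2]], "999.9")
})

test_that("duplicate keys survive read -> write -> read without loss", {
  fix <- cachedFixture(seed = 31, nSamples = 2, nMetabolites = 3)
  doc <- fix$document
  i <- which(doc@sections@keys == "MS_METABOLITE_DATA")
  tab <- doc@sections@values[[i]]
  tab@rows[[2]] <- mapAppend(tab@rows[[2]], "S002", "111.1")
  doc@sections@values[[i]] <- tab
  once <- parseMWTabJSON(formatMWTabJSON(doc))
  twice <- parseMWTabJSON(formatMWTabJSON(once))
  expect_identical(mapGet(getSection(twice, "MS_METABOLITE_DATA")@rows[[2]], "S002"),
                   mapGet(tab@rows[[2]], "S002"))
  expect_identical(formatMWTabJSON(once), formatMWTabJSON(twice))
})

test_that("duplicate-free output is standard JSON for any conforming reader", {
  fix <- cachedFixture(seed = 31, nSamples = 2, nMetabolites = 3)
  parsed <- jsonlite::fromJSON(fix$json, simplifyVector = FALSE)
  expect_true("METABOLOMICS WORKBENCH" %in% names(parsed))
  expect_equal(length(parsed[["SUBJECT_SAMPLE_FACTORS"]]), 2)
})

test_that("top-level duplicate keys are refused", {
  d <- injectParseDefect("json_top_level_duplicate", seed = 5)
  expect_error(parseMWTabJSON(d$text),
               class = "mwtab_parse_error_json_top_level_duplicate")
})

test_that("a non-object table row is refused by default and skipped with force", {
  d <- injectParseDefect("json_false_row", seed = 5)
  expect_error(parseMWTabJSON(d$text),
               class = "mwtab_parse_error_json_false_row")
  expect_warning(doc <- parseMWTabJSON(d$text, force = TRUE), "skipping")
  nAll <- length(getSection(cachedFixture(seed = 5, nSamples = 4,
                                          nMetabolites = 6)$document,
                            "MS_METABOLITE_DATA")@rows)
  expect_equal(length(getSection(doc, "MS_METABOLITE_DATA")@rows), nAll - 1)
})

test_that("malformed JSON is a classed parse refusal", {
  d <- injectParseDefect("json_malformed", seed = 5)
  expect_error(parseMWTabJSON(d$text), class = "mwtab_parse_error_json_malformed")
})

test_that("flat top-level header attributes are accepted on read", {
  json <- '{"STUDY_ID": "ST000123", "VERSION": "1", "PROJECT": {"PROJECT_TITLE": "t"}}'
  doc <- parseMWTabJSON(json)
  hf <- headerFields(doc)
  expect_equal(hf[["STUDY_ID"]], "ST000123")
  expect_true("PROJECT" %in% sectionNames(doc))
})

test_that("null and absent subsection values stay distinct through JSON", {
  json <- '{"MS": {"ION_MODE": null, "MS_TYPE": "ESI"}}'
  doc <- parseMWTabJSON(json)
  items <- getSection(doc, "MS")@items
  expect_true(mapHas(items, "ION_MODE"))
  expect_null(mapGet(items, "ION_MODE")[[1]])
  expect_false(mapHas(items, "MS_COMMENTS"))
  # null survives a JSON round trip
  back <- parseMWTabJSON(formatMWTabJSON(doc))
  expect_null(mapGet(getSection(back, "MS")@items, "ION_MODE")[[1]])
})
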