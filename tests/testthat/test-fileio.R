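test_that("reading a written fixture reproduces the document", {
  fix <- cachedFixture(seed = 21, nSamples = 3, nMetabolites = 5)
  path <- tempfile(fileext = ".txt")
  writeMWTab(fix$document, path)
  again <- readMWTab(path)
  expect_equal(nrow(compareDocuments(fix$document, again)), 0)
})

test_that("duplicated sample columns survive a read (both retained)", {
  d <- injectDefect(8, "mwtab", seed = 6)
  doc <- parseMWTab(d$text)
  tab <- getSection(doc, "MS_METABOLITE_DATA")
  dupCol <- tab@columns[duplicated(tab@columns)][1]
  expect_equal(sum(tab@columns == dupCol), 2)
  expect_length(mapGet(tab@rows[[1]], dupCol), 2)
  expect_gt(nrow(parseAnnotations(doc)$duplicateSampleColumns), 0)
})

test_that("non-ASCII values survive write/read in both formats", {
  fix <- generateFixture(seed = 23, nSamples = 2, nMetabolites = 3)
  doc <- fix$document
  i <- which(doc@sections@keys == "COLLECTION")
  blk <- doc@sections@values[[i]]
  blk@items <- mapSet(blk@items, "COLLECTION_SUMMARY",
                      "Plasma à jeûn — 4°C, µL aliquots")
  doc@sections@values[[i]] <- blk
  for (fmt in c("mwtab", "json")) {
    p <- tempfile()
    writeFileUTF8(mwtabr:::formatDocument(doc, fmt), p)
    back <- if (fmt == "json") readMWTabJSON(p) else readMWTab(p)
    v <- mapGetOne(getSection(back, "COLLECTION")@items, "COLLECTION_SUMMARY")
    expect_equal(v, "Plasma à jeûn — 4°C, µL aliquots")
  }
})

test_that("two writes of one document are byte-identical", {
  fix <- cachedFixture(seed = 21, nSamples = 3, nMetabolites = 5)
  expect_identical(formatMWTab(fix$document), formatMWTab(fix$document))
  expect_identical(formatMWTabJSON(fix$document), formatMWTabJSON(fix$document))
  # write -> read -> write fixed point
  doc2 <- parseMWTab(formatMWTab(fix$document))
  expect_identical(formatMWTab(fix$document), formatMWTab(doc2))
  doc3 <- parseMWTabJSON(formatMWTabJSON(fix$document))
  expect_identical(formatMWTabJSON(fix$document), formatMWTabJSON(doc3))
})

test_that("missing output directories are created, not fatal", {
  dir <- file.path(tempdir(), "nested", "deeply", basename(tempfile()))
  p <- file.path(dir, "out.txt")
  fix <- cachedFixture(seed = 21, nSamples = 3, nMetabolites = 5)
  expect_no_error(writeMWTab(fix$document, p))
  expect_true(file.exists(p))
})

test_that("a malformed file does not abort a batch", {
  fix <- cachedFixture(seed = 21, nSamples = 3, nMetabolites = 5)
  good1 <- writeTempFixture(fix, "mwtab")
  bad <- tempfile(fileext = ".txt")
  writeLines(strsplit(injectParseDefect("ssf_extra_equals", seed = 8)$text,
                      "\n")[[1]], bad)
  good2 <- writeTempFixture(fix, "json")
  res <- processBatch(c(good1, bad, good2), readMWTabAny)
  expect_equal(nrow(res), 3)
  expect_equal(res$outcome, c("ok", "parse_error", "ok"))
  expect_match(res$detail[2], "=")
})

test_that("an empty batch yields an empty result", {
  res <- processBatch(character(0), readMWTab)
  expect_equal(nrow(res), 0)
})

test_that("batch always produces one record per input", {
  fix <- cachedFixture(seed = 21, nSamples = 3, nMetabolites = 5)
  inputs <- c(writeTempFixture(fix, "mwtab"), "/nonexistent/file.txt",
              writeTempFixture(fix, "json"))
  res <- processBatch(inputs, readMWTabAny)
  expect_equal(nrow(res), length(inputs))
  expect_equal(sum(res$outcome == "ok"), 2)
})
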