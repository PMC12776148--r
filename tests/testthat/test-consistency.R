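test_that("identical documents compare as consistent", {
  fix <- cachedFixture(seed = 81, nSamples = 3, nMetabolites = 5)
  expect_equal(nrow(compareDocuments(fix$document, fix$document)), 0)
  expect_true(documentsConsistent(fix$document, fix$document))
})

test_that("a section present in one document only is a SectionKeys difference", {
  fix <- cachedFixture(seed = 81, nSamples = 3, nMetabolites = 5)
  a <- fix$document
  b <- mwtabr:::dropSection(a, "CHROMATOGRAPHY")
  d <- compareDocuments(a, b)
  expect_equal(d$category, "SectionKeys")
  expect_equal(d$path, "CHROMATOGRAPHY")
  # the bogus #FACTORS empty section counts the same way
  lines <- strsplit(fix$mwtab, "\n")[[1]]
  withFactors <- parseMWTab(append(lines, "#FACTORS",
                                   after = grep("^#ANALYSIS$", lines) - 1))
  d2 <- compareDocuments(withFactors, fix$document)
  expect_equal(d2$category, "SectionKeys")
  expect_equal(d2$path, "FACTORS")
})

test_that("a subsection present in one only is a SubsectionKeys difference", {
  fix <- cachedFixture(seed = 81, nSamples = 3, nMetabolites = 5)
  a <- fix$document
  b <- mwtabr:::mutateBlock(a, "MS", function(items)
    mapAppend(items, "MS_RESULTS_FILE", "extra.zip"))
  d <- compareDocuments(a, b)
  expect_equal(d$category, "SubsectionKeys")
  expect_equal(d$path, "MS/MS_RESULTS_FILE")
})

test_that("differing values and differing shapes are distinguished", {
  a <- parseMWTabJSON('{"MS": {"MS_TYPE": "ESI"}}')
  b <- parseMWTabJSON('{"MS": {"MS_TYPE": "EI"}}')
  expect_equal(compareDocuments(a, b)$category, "SubsectionValues")
  c_ <- parseMWTabJSON('{"MS": {"MS_TYPE": ["ESI"]}}')
  d <- compareDocuments(a, c_)
  expect_equal(d$category, "SubsectionType")
  expect_match(d$detail, "scalar.*list")
})

test_that("table and SSF differences carry the DATA and SSF categories", {
  fix <- cachedFixture(seed = 81, nSamples = 3, nMetabolites = 5)
  a <- fix$document
  b <- mwtabr:::mutateTable(a, "DATA", function(t)
    mwtabr:::setRowCell(t, 1, "S001", "0.0"))
  expect_equal(unique(compareDocuments(a, b)$category), "DATA")
  c_ <- mwtabr:::mutateSSF(a, function(ssf) {
    ssf@records[[1]]@factors <- mapSet(ssf@records[[1]]@factors,
                                       "Treatment", "Other")
    ssf
  })
  expect_equal(unique(compareDocuments(a, c_)$category), "SSF")
})

test_that("comparison is symmetric in categories and counts", {
  fix <- cachedFixture(seed = 81, nSamples = 3, nMetabolites = 5)
  a <- fix$document
  b <- mwtabr:::dropSection(
    mwtabr:::mutateBlock(a, "MS", function(items) mapDrop(items, "ION_MODE")),
    "CHROMATOGRAPHY")
  expect_identical(summarizeDifferences(compareDocuments(a, b)),
                   summarizeDifferences(compareDocuments(b, a)))
})

test_that("summaries tally per category with zeros included", {
  s0 <- summarizeDifferences(compareDocuments(
    cachedFixture(seed = 81, nSamples = 3, nMetabolites = 5)$document,
    cachedFixture(seed = 81, nSamples = 3, nMetabolites = 5)$document))
  expect_true(all(s0 == 0))
  expect_setequal(names(s0), c("DATA", "SSF", "SectionKeys", "SubsectionKeys",
                               "SubsectionValues", "SubsectionType"))
})

test_that("an mwTab parse and the JSON parse of its conversion are consistent", {
  for (seed in c(82, 83)) {
    fix <- cachedFixture(seed = seed, nSamples = 3, nMetabolites = 5,
                         includeExtended = seed == 83)
    jsonDoc <- parseMWTabJSON(formatMWTabJSON(fix$document))
    expect_equal(nrow(compareDocuments(fix$document, jsonDoc)), 0)
  }
})

test_that("header attributes are compared as a pseudo-section", {
  fix <- cachedFixture(seed = 81, nSamples = 3, nMetabolites = 5)
  a <- fix$document
  b <- mwtabr:::mutateBlock(a, "METABOLOMICS WORKBENCH", function(items)
    mapSet(items, "VERSION", "2"))
  d <- compareDocuments(a, b)
  expect_equal(d$category, "SubsectionValues")
  expect_equal(d$path, "METABOLOMICS WORKBENCH/VERSION")
})
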