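test_that("headerFields retrieves present attributes and omits absent ones", {
  fix <- cachedFixture(seed = 11, nSamples = 3, nMetabolites = 4)
  hf <- headerFields(fix$document)
  expect_match(hf[["STUDY_ID"]], "^ST[0-9]{6}$")
  expect_equal(hf[["VERSION"]], "1")
  expect_false("NOT_A_FIELD" %in% names(hf))
})

test_that("a blank header attribute is present with an empty value", {
  fix <- cachedFixture(seed = 11, nSamples = 3, nMetabolites = 4)
  lines <- strsplit(fix$mwtab, "\n")[[1]]
  # blank the PROJECT_ID on the header line, then re-add it as an empty item
  lines[1] <- sub(" PROJECT_ID:PR[0-9]{6}", "", lines[1])
  lines <- append(lines, "PROJECT_ID\t", after = 1)
  doc <- parseMWTab(lines)
  hf <- headerFields(doc)
  expect_true("PROJECT_ID" %in% names(hf))
  expect_identical(hf[["PROJECT_ID"]], "")
})

test_that("table/matrix conversion round-trips, duplicated columns included", {
  tab <- MWTabTable(role = "METABOLITES",
                    columns = c("Metabolite", "S1", "S1"),
                    rows = list(
                      DuplicatesMap(c("Metabolite", "S1", "S1"),
                                    list("glucose", "1", "2")),
                      DuplicatesMap(c("Metabolite", "S1", "S1"),
                                    list("alanine", "3", "4"))))
  m <- tableToMatrix(tab)
  expect_equal(dim(m), c(3, 3))
  expect_equal(m[1, ], c("Metabolite", "S1", "S1"))
  back <- matrixToTable(m, template = tab)
  expect_equal(back@columns, tab@columns)
  expect_equal(lapply(back@rows, mapValues), lapply(tab@rows, mapValues))
})

test_that("table/matrix conversion survives degenerate shapes", {
  # brute force over tiny shapes, empty table included
  for (ncol in 1:3) for (nrow in 0:2) {
    cols <- sprintf("C%d", seq_len(ncol))
    rows <- lapply(seq_len(nrow), function(i)
      DuplicatesMap(cols, as.list(sprintf("%d.%d", i, seq_len(ncol)))))
    tab <- MWTabTable(role = "METABOLITES", columns = cols, rows = rows)
    m <- tableToMatrix(tab)
    expect_equal(dim(m), c(nrow + 1, ncol))
    back <- matrixToTable(m, template = tab)
    expect_equal(back@columns, cols)
    expect_equal(lapply(back@rows, mapValues), lapply(rows, mapValues))
  }
})

test_that("non-harmonized rows are refused by the matrix layout", {
  tab <- MWTabTable(role = "METABOLITES", columns = c("A", "B"),
                    rows = list(DuplicatesMap("A", list("1"))))
  expect_error(tableToMatrix(tab), "not harmonized")
})

test_that("annotations on generator-produced clean fixtures are empty", {
  for (seed in c(2, 9)) {
    fix <- cachedFixture(seed = seed, nSamples = 3, nMetabolites = 4)
    ann <- parseAnnotations(fix$document)
    expect_true(all(vapply(ann, NROW, integer(1)) == 0))
  }
})

test_that("model -> serialize -> parse is a fixed point in both formats", {
  fix <- cachedFixture(seed = 13, nSamples = 4, nMetabolites = 6,
                       includeExtended = TRUE)
  doc <- fix$document
  again <- parseMWTab(formatMWTab(doc))
  expect_equal(nrow(compareDocuments(doc, again)), 0)
  viaJson <- parseMWTabJSON(formatMWTabJSON(doc))
  expect_equal(nrow(compareDocuments(doc, viaJson)), 0)
})
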