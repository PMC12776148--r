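test_that("the check registry enumerates IDs 1 to 36 exactly once", {
  reg <- checkRegistry()
  expect_identical(sort(reg$id), 1:36)
  expect_identical(reg$applicability[reg$id %in% c(1, 2, 3, 8, 30)],
                   rep("mwtab", 5))
  expect_true(all(nzchar(reg$short_name)))
  expect_true(all(nzchar(reg$categories)))
})

test_that("a clean fixture validates with zero messages in both formats", {
  fix <- cachedFixture(seed = 61, nSamples = 4, nMetabolites = 6,
                       includeExtended = TRUE)
  expect_equal(nrow(validateDocument(fix$document)), 0)
  expect_equal(nrow(validateDocument(parseMWTabJSON(fix$json))), 0)
  nm <- cachedFixture(seed = 62, nSamples = 3, nMetabolites = 5, mode = "NM")
  expect_equal(nrow(validateDocument(nm$document)), 0)
})

test_that("duplicate sample IDs, factors and additional data are detected", {
  doc4 <- defectiveDocument(4, "mwtab", seed = 63)
  expect_true(4 %in% validateDocument(doc4)$id)
  doc5 <- defectiveDocument(5, "json", seed = 63)
  expect_true(5 %in% validateDocument(doc5)$id)
  doc6 <- defectiveDocument(6, "mwtab", seed = 63)
  expect_true(6 %in% validateDocument(doc6)$id)
})

test_that("a data-table sample missing from SSF is a consistency finding", {
  doc <- defectiveDocument(7, "json", seed = 63)
  msgs <- validateDocument(doc)
  hit <- msgs[msgs$id == 7, ]
  expect_equal(nrow(hit), 1)
  expect_true(messageHasCategory(hit, "consistency"))
})

test_that("metabolite set differences between DATA and METABOLITES are found", {
  m12 <- validateDocument(defectiveDocument(12, "mwtab", seed = 64))
  hit <- m12[m12$id == 12, ]
  expect_equal(nrow(hit), 1)
  expect_true(messageHasCategory(hit, "consistency"))
  m9 <- validateDocument(defectiveDocument(9, "json", seed = 64))
  expect_true(9 %in% m9$id)
})

test_that("duplicate and blank metabolite names are found", {
  expect_true(11 %in% validateDocument(defectiveDocument(11, "mwtab", seed = 65))$id)
  expect_true(14 %in% validateDocument(defectiveDocument(14, "json", seed = 65))$id)
  expect_true(10 %in% validateDocument(defectiveDocument(10, "mwtab", seed = 65))$id)
  expect_true(13 %in% validateDocument(defectiveDocument(13, "json", seed = 65))$id)
})

test_that("a document with neither MS nor NM section is flagged", {
  doc <- defectiveDocument(32, "mwtab", seed = 66)
  msgs <- validateDocument(doc)
  expect_true(32 %in% msgs$id)
  expect_equal(msgs$severity[msgs$id == 32], "error")
})

test_that("a header-like metabolite name is flagged", {
  msgs <- validateDocument(defectiveDocument(23, "mwtab", seed = 66))
  expect_true(23 %in% msgs$id)
  expect_match(msgs$message[msgs$id == 23], "metabolite_name")
})

test_that("near-constant columns fire at 90% but not at 100% or 80%", {
  fix <- generateFixture(seed = 67, nSamples = 2, nMetabolites = 10)
  withShare <- function(nMajor) {
    doc <- fix$document
    i <- which(doc@sections@keys == "METABOLITES")
    tab <- doc@sections@values[[i]]
    vals <- c(rep("A", nMajor), sprintf("B%d", seq_len(10 - nMajor)))
    tab <- mwtabr:::addTableColumn(tab, "batch", vals)
    doc@sections@values[[i]] <- tab
    validateDocument(doc)
  }
  expect_true(28 %in% withShare(9)$id)    # 90%
  expect_false(28 %in% withShare(10)$id)  # constant
  expect_false(28 %in% withShare(8)$id)   # 80%
})

test_that("an all-null column is a null column, not a near-constant one", {
  msgs <- validateDocument(defectiveDocument(27, "json", seed = 67))
  expect_true(27 %in% msgs$id)
  expect_false(28 %in% msgs$id)
})

test_that("an all-distinct column is neither null nor near-constant", {
  fix <- cachedFixture(seed = 61, nSamples = 4, nMetabolites = 6,
                       includeExtended = TRUE)
  msgs <- validateDocument(fix$document)
  expect_false(any(c(27, 28) %in% msgs$id))
})

test_that("standard-column findings carry the documented severities", {
  m15 <- validateDocument(defectiveDocument(15, "mwtab", seed = 68))
  hit <- m15[m15$id == 15, ]
  expect_equal(hit$severity, "warning")
  expect_match(hit$message, "moverz_quant")
  m17 <- validateDocument(defectiveDocument(17, "json", seed = 68))
  expect_equal(m17$severity[m17$id == 17], "warning")
  m16 <- validateDocument(defectiveDocument(16, "mwtab", seed = 68))
  expect_equal(m16$severity[m16$id == 16], "error")
})

test_that("mixed polarity values are flagged", {
  msgs <- validateDocument(defectiveDocument(31, "json", seed = 68))
  hit <- msgs[msgs$id == 31, ]
  expect_equal(nrow(hit), 1)
  expect_match(hit$message, "POS")
})

test_that("factor mismatches are found in mwTab sources only", {
  d <- injectDefect(3, "mwtab", seed = 69)
  doc <- parseMWTab(d$text)
  expect_true(3 %in% validateDocument(doc)$id)
  # same content via JSON has no second factor source
  jsonDoc <- parseMWTabJSON(formatMWTabJSON(doc))
  expect_false(3 %in% validateDocument(jsonDoc)$id)
})

test_that("messages are worded for the source format", {
  m <- validateDocument(defectiveDocument(24, "mwtab", seed = 70))
  j <- validateDocument(defectiveDocument(24, "json", seed = 70))
  expect_match(m$message[m$id == 24 & m$subsection == "SUBJECT_TYPE"], "subsection")
  expect_match(j$message[j$id == 24 & j$subsection == "SUBJECT_TYPE"], "key")
})

test_that("repeated findings of one root cause are condensed to one message", {
  fix <- generateFixture(seed = 71, nSamples = 2, nMetabolites = 8)
  doc <- fix$document
  i <- which(doc@sections@keys == "METABOLITES")
  tab <- doc@sections@values[[i]]
  for (r in 1:5) tab <- mwtabr:::setRowCell(tab, r, "kegg_id", "not-a-kegg")
  doc@sections@values[[i]] <- tab
  msgs <- validateDocument(doc)
  hit <- msgs[msgs$id == 16, ]
  expect_equal(nrow(hit), 1)
  expect_equal(hit$occurrences, 5)
})

test_that("validation output is deterministic across repeated calls", {
  doc <- defectiveDocument(9, "mwtab", seed = 72)
  expect_identical(validateDocument(doc), validateDocument(doc))
})

test_that("status classification follows the message severities", {
  expect_equal(categorizeMessages(validateDocument(
    cachedFixture(seed = 61, nSamples = 4, nMetabolites = 6,
                  includeExtended = TRUE)$document))$status, "Passing")
  w <- categorizeMessages(validateDocument(defectiveDocument(15, "mwtab", seed = 73)))
  expect_equal(w$status, "Warnings Only")
  expect_false(w$hasValueErrors)
  e <- categorizeMessages(validateDocument(defectiveDocument(24, "mwtab", seed = 73)))
  expect_equal(e$status, "Errors")
  expect_true(e$hasFormatErrors)
})
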