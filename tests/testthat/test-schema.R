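test_that("accession patterns accept and reject the right shapes", {
  expect_true(grepl(idPattern("analysis"), "AN002312"))
  expect_false(grepl(idPattern("study"), "AN002312"))
  expect_true(grepl(idPattern("study"), "ST000001"))
  expect_error(idPattern("bogus"))
})

test_that("project pattern agrees with a brute-force oracle on sampled candidates", {
  set.seed(123)
  oracle <- function(x) {
    # independent re-implementation: prefix test + digit test, no regex
    nchar(x) == 8 && substr(x, 1, 2) == "PR" &&
      all(strsplit(substr(x, 3, 8), "")[[1]] %in% as.character(0:9))
  }
  candidates <- c(
    sprintf("PR%06d", sample(0:999999, 300)),
    sprintf("PR%05d", sample(0:99999, 100)),
    sprintf("PR%07d", sample(0:9999999, 100)),
    sprintf("ST%06d", sample(0:999999, 100)),
    sprintf("PR%05dX", sample(0:99999, 100)),
    replicate(400, paste(sample(c(LETTERS, 0:9), 8, replace = TRUE),
                         collapse = "")))
  got <- grepl(idPattern("project"), candidates)
  want <- vapply(candidates, oracle, logical(1), USE.NAMES = FALSE)
  expect_identical(got, want)
})

test_that("a missing required subsection yields a condensed format error", {
  doc <- defectiveDocument(24, "mwtab", seed = 51)
  msgs <- validateStructure(doc)
  hit <- msgs[msgs$section == "SUBJECT" & msgs$subsection == "SUBJECT_TYPE", ]
  expect_equal(nrow(hit), 1)
  expect_equal(hit$id, 24)
  expect_equal(hit$severity, "error")
  expect_true(messageHasCategory(hit, "format"))
  expect_match(hit$message, "not present")
})

test_that("a fully valid fixture yields no structural messages", {
  fix <- cachedFixture(seed = 51, nSamples = 3, nMetabolites = 5)
  expect_equal(nrow(validateStructure(fix$document)), 0)
})

test_that("null/blank values and absent keys are worded distinctly", {
  docBlank <- parseMWTabJSON('{"SUBJECT": {"SUBJECT_TYPE": "", "SUBJECT_SPECIES": "Homo sapiens"}}')
  docNull <- parseMWTabJSON('{"SUBJECT": {"SUBJECT_TYPE": null, "SUBJECT_SPECIES": "Homo sapiens"}}')
  docAbsent <- parseMWTabJSON('{"SUBJECT": {"SUBJECT_SPECIES": "Homo sapiens"}}')
  msg <- function(doc) {
    m <- validateStructure(doc)
    m$message[m$section == "SUBJECT" & m$subsection == "SUBJECT_TYPE"]
  }
  expect_match(msg(docBlank), "blank")
  expect_match(msg(docNull), "null")
  expect_match(msg(docAbsent), "not present")
  expect_length(unique(c(msg(docBlank), msg(docNull), msg(docAbsent))), 3)
})

test_that("a voltage-like subsection with units of power is a value-space violation", {
  fix <- generateFixture(seed = 52, nSamples = 2, nMetabolites = 3)
  doc <- fix$document
  i <- which(doc@sections@keys == "MS")
  blk <- doc@sections@values[[i]]
  blk@items <- mapAppend(blk@items, "CAPILLARY_VOLTAGE", "5 W")
  doc@sections@values[[i]] <- blk
  msgs <- validateStructure(doc)
  hit <- msgs[msgs$subsection == "CAPILLARY_VOLTAGE", ]
  expect_equal(nrow(hit), 1)
  expect_true(messageHasCategory(hit, "value"))
  expect_true(messageHasCategory(hit, "format"))
})

test_that("the five newly required CHROMATOGRAPHY attributes are enforced", {
  fix <- generateFixture(seed = 53, nSamples = 2, nMetabolites = 3, mode = "MS")
  doc <- fix$document
  expect_equal(nrow(validateStructure(doc)), 0)
  required <- c("CHROMATOGRAPHY_TYPE", "INSTRUMENT_NAME", "COLUMN_NAME",
                "SOLVENT_A", "SOLVENT_B")
  i <- which(doc@sections@keys == "CHROMATOGRAPHY")
  blk <- doc@sections@values[[i]]
  for (k in required) blk@items <- mapDrop(blk@items, k)
  doc@sections@values[[i]] <- blk
  msgs <- validateStructure(doc)
  hit <- msgs[msgs$section == "CHROMATOGRAPHY", ]
  expect_setequal(hit$subsection, required)
})

test_that("schema rules round-trip through the config file format", {
  rules <- defaultSchemaRules()
  p <- tempfile(fileext = ".tsv")
  writeSchemaRules(rules, p)
  back <- readSchemaRules(p)
  expect_equal(back$section, rules$section)
  expect_equal(back$required, rules$required)
  expect_equal(back$pattern, rules$pattern)
})
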