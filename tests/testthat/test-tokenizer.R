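test_that("classifyLine maps each line shape to its token", {
  expect_equal(classifyLine("#PROJECT", 1)$kind, "SectionHeader")
  expect_equal(classifyLine("#PROJECT", 1)$name, "PROJECT")
  tok <- classifyLine("PR:PROJECT_TITLE\tA title", 2)
  expect_equal(tok[c("kind", "prefix", "key", "value")],
               list(kind = "Item", prefix = "PR", key = "PROJECT_TITLE",
                    value = "A title"))
  expect_equal(classifyLine("MS_METABOLITE_DATA_START", 3)$kind, "TableBegin")
  expect_equal(classifyLine("METABOLITES_END", 4)$kind, "TableEnd")
  expect_equal(classifyLine("SUBJECT_SAMPLE_FACTORS\t-\tS1\t\t", 5)$kind, "SSFLine")
  expect_equal(classifyLine("", 6)$kind, "Blank")
  expect_equal(classifyLine("glucose\t1\t2", 7, inTable = TRUE)$kind, "TableRow")
})

test_that("header line carries its accession items", {
  tok <- classifyLine("#METABOLOMICS WORKBENCH STUDY_ID:ST000001 ANALYSIS_ID:AN000001", 1)
  expect_equal(tok$name, "METABOLOMICS WORKBENCH")
  expect_equal(tok$items[[1]], list(key = "STUDY_ID", value = "ST000001"))
  expect_equal(tok$items[[2]], list(key = "ANALYSIS_ID", value = "AN000001"))
})

test_that("a section-code line without its tab is refused with its line number", {
  err <- tryCatch(classifyLine("CO:COLLECTION_SUMMARY some text", 17),
                  error = function(e) e)
  expect_s3_class(err, "mwtab_parse_error_missing_tab")
  expect_equal(err$lineNo, 17)
})

test_that("an uncapitalized prefix-less line outside a table is an orphan", {
  err <- tryCatch(classifyLine("continuation of a value", 9),
                  error = function(e) e)
  expect_s3_class(err, "mwtab_parse_error_orphan_line")
  expect_equal(err$lineNo, 9)
})

test_that("SSF lines parse factors on | and : and additional data on ; and =", {
  rec <- parseSSFLine(c("SUBJECT_SAMPLE_FACTORS", "SU1", "S1",
                        "Treatment:Control | Time:4h",
                        "RAW=a.raw; batch=1"))
  expect_equal(rec@sampleId, "S1")
  expect_equal(as.list(rec@factors), list(Treatment = "Control", Time = "4h"))
  expect_equal(as.list(rec@additionalData), list(RAW = "a.raw", batch = "1"))
})

test_that("ambiguous SSF fragments are refused, not guessed at", {
  expect_error(parseSSFLine(c("SSF", "s", "S1", "Dose:5:mg", "")),
               class = "mwtab_parse_error_ssf")
  expect_error(parseSSFLine(c("SSF", "s", "S1", "", "RAW=a=b.raw")),
               class = "mwtab_parse_error_ssf")
  expect_error(parseSSFLine(c("SSF", "s", "S1", "", "RAW=a.raw batch=1")),
               class = "mwtab_parse_error_ssf")
})

test_that("harmonizeRow pads short rows and drops empty overflow", {
  header <- c("Metabolite", "S1", "S2")
  expect_equal(harmonizeRow(header, c("m1", "1", "2", "", ""))$cells,
               c("m1", "1", "2"))
  expect_equal(harmonizeRow(header, c("m1", "1"))$cells, c("m1", "1", ""))
  expect_equal(harmonizeRow(header, c("m1", "1", "2"))$cells, c("m1", "1", "2"))
  expect_null(harmonizeRow(header, c("m1", "1", "2", "", ""))$mismatch)
})

test_that("non-empty overflow cells are recorded, not refused", {
  h <- harmonizeRow(c("A", "B"), c("1", "2", "3"))
  expect_equal(h$mismatch, 3)
  expect_length(h$cells, 2)
})

test_that("harmonizeRow is idempotent", {
  set.seed(7)
  for (i in 1:20) {
    header <- sprintf("C%d", seq_len(sample(1:6, 1)))
    cells <- as.character(sample(c("", "x", "9"), sample(0:9, 1), replace = TRUE))
    once <- harmonizeRow(header, cells)$cells
    expect_identical(harmonizeRow(header, once)$cells, once)
  }
})

test_that("tokenizing a clean fixture yields no bogus sections", {
  fix <- cachedFixture(seed = 3, nSamples = 3, nMetabolites = 4)
  lexed <- tokenizeMWTab(fix$mwtab)
  expect_length(lexed$bogusSectionLines, 0)
})

test_that("a second *_DATA_END between rows is refused", {
  d <- injectParseDefect("multiple_data_end", seed = 4)
  expect_error(parseMWTab(d$text), class = "mwtab_parse_error_multiple_data_end")
})

test_that("a #FACTORS line creates an annotated empty section", {
  fix <- cachedFixture(seed = 3, nSamples = 3, nMetabolites = 4)
  lines <- strsplit(fix$mwtab, "\n")[[1]]
  i <- grep("^#ANALYSIS$", lines)
  lines <- append(lines, "#FACTORS", after = i - 1)
  doc <- parseMWTab(lines)
  expect_true("FACTORS" %in% sectionNames(doc))
  expect_length(parseAnnotations(doc)$bogusSectionLines, 1)
})

test_that("parse errors report 1-based line numbers present in the input", {
  fix <- cachedFixture(seed = 3, nSamples = 3, nMetabolites = 4)
  lines <- strsplit(fix$mwtab, "\n")[[1]]
  for (cls in c("missing_tab", "embedded_carriage_return", "ssf_extra_colon")) {
    d <- injectParseDefect(cls, seed = 3)
    err <- tryCatch(parseMWTab(d$text), error = function(e) e)
    expect_true(inherits(err, "mwtab_parse_error"))
    expect_true(!is.na(err$lineNo) && err$lineNo >= 1 &&
                  err$lineNo <= length(strsplit(d$text, "\n")[[1]]))
  }
})
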