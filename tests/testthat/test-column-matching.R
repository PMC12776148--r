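test_that("normalization unifies separator and case variants", {
  expect_equal(normalizeColumnName("Ret Time"), "ret_time")
  expect_equal(normalizeColumnName("retention_time"),
               normalizeColumnName("retention time"))
  expect_equal(normalizeColumnName("  RET--TIME "), "ret_time")
  expect_equal(normalizeColumnName(""), "")
  # idempotent
  x <- c("Ret Time", "m/z", "KEGG ID")
  expect_identical(normalizeColumnName(normalizeColumnName(x)),
                   normalizeColumnName(x))
})

test_that("known variants match their standard names", {
  expect_equal(matchColumnName("ret_time"), "retention_time")
  expect_equal(matchColumnName("Retention Time"), "retention_time")
  expect_equal(matchColumnName("m/z"), "moverz_quant")
  expect_equal(matchColumnName("mz"), "moverz_quant")
  expect_equal(matchColumnName("KEGG"), "kegg_id")
  expect_equal(matchColumnName("zzz_unrelated"), character(0))
})

test_that("findStandardColumns flags rename candidates but not canonical spellings", {
  out <- findStandardColumns(c("Metabolite", "mz", "retention time"))
  expect_false(out[[1]]$renameCandidate)   # canonical anchor
  expect_true(out[[2]]$renameCandidate)
  expect_true(out[[3]]$renameCandidate)
  allCanon <- findStandardColumns(c("Metabolite", "moverz_quant", "kegg_id"))
  expect_false(any(vapply(allCanon, `[[`, logical(1), "renameCandidate")))
})

test_that("a name matching two finders is reported as a multi-match", {
  out <- findStandardColumns("retention")[[1]]
  expect_setequal(out$matches, c("retention_time", "retention_index"))
  expect_true(length(out$matches) > 1)
})

test_that("value validation flags non-matching non-empty values only", {
  expect_equal(validateColumnValues("kegg_id", c("C00031", "banana")), 2L)
  expect_equal(validateColumnValues("kegg_id", c("", "", NA)), integer(0))
  expect_equal(validateColumnValues("retention_index_type", c("anything")),
               integer(0))  # no value rule
  expect_error(validateColumnValues("not_a_canonical", "x"), "unknown")
})

test_that("kegg value rule agrees with an independent oracle on random strings", {
  set.seed(7)
  oracle <- function(v) {
    # character-wise re-implementation, no regex
    if (nchar(v) != 6) return(FALSE)
    ch <- strsplit(v, "")[[1]]
    ch[1] %in% c("C", "D", "G", "R", "M") && all(ch[-1] %in% as.character(0:9))
  }
  pool <- c("C", "D", "G", "R", "M", "X", "c", as.character(0:9))
  cand <- c(sprintf("C%05d", sample(0:99999, 50)),
            replicate(150, paste(sample(pool, sample(4:8, 1), replace = TRUE),
                                 collapse = "")))
  got <- vapply(cand, function(v)
    length(validateColumnValues("kegg_id", v)) == 0, logical(1),
    USE.NAMES = FALSE)
  want <- vapply(cand, oracle, logical(1), USE.NAMES = FALSE)
  expect_identical(got, want)
})

test_that("the registry is self-consistent", {
  reg <- defaultColumnRegistry()
  for (fdr in reg) {
    hits <- matchColumnName(fdr@canonical, reg)
    expect_true(fdr@canonical %in% hits,
                info = paste("canonical fails own rules:", fdr@canonical))
    others <- setdiff(hits, c(fdr@canonical, fdr@exclusiveWith))
    expect_length(others, 0)
  }
})

test_that("implied partners are symmetric", {
  reg <- defaultColumnRegistry()
  expect_true("retention_index_type" %in% reg[["retention_index"]]@impliedPartners)
  expect_true("retention_index" %in% reg[["retention_index_type"]]@impliedPartners)
  for (fdr in reg)
    for (p in fdr@impliedPartners)
      expect_true(fdr@canonical %in% reg[[p]]@impliedPartners,
                  info = paste(fdr@canonical, "->", p))
})

test_that("the registry round-trips through its config file format", {
  reg <- defaultColumnRegistry()
  p <- tempfile(fileext = ".json")
  writeColumnRegistry(reg, p)
  back <- readColumnRegistry(p)
  expect_equal(length(back), length(reg))
  expect_equal(names(back), names(reg))
  expect_equal(back[["kegg_id"]]@valuePattern, reg[["kegg_id"]]@valuePattern)
  expect_equal(back[["retention_index"]]@impliedPartners,
               reg[["retention_index"]]@impliedPartners)
})
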