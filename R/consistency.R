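#' @include json-io.R
NULL

CONSISTENCY_CATEGORIES <- c("DATA", "SSF", "SectionKeys", "SubsectionKeys",
                            "SubsectionValues", "SubsectionType")

newDifference <- function(category, path, detail) {
  data.frame(category = category, path = path, detail = detail,
             stringsAsFactors = FALSE)
}

noDifferences <- function() {
  data.frame(category = character(0), path = character(0), detail = character(0),
             stringsAsFactors = FALSE)
}

valueShape <- function(v) if (is.list(v)) "list" else "scalar"

compareBlocks <- function(a, b, section, dfs) {
  ka <- unique(a@items@keys); kb <- unique(b@items@keys)
  for (k in setdiff(ka, kb))
    dfs <- rbind(dfs, newDifference("SubsectionKeys", paste0(section, "/", k),
                                    "subsection present in first document only"))
  for (k in setdiff(kb, ka))
    dfs <- rbind(dfs, newDifference("SubsectionKeys", paste0(section, "/", k),
                                    "subsection present in second document only"))
  for (k in intersect(ka, kb)) {
    va <- mapGet(a@items, k); vb <- mapGet(b@items, k)
    if (length(va) != length(vb)) {
      dfs <- rbind(dfs, newDifference("SubsectionValues", paste0(section, "/", k),
        sprintf("%d occurrence(s) vs %d", length(va), length(vb))))
      next
    }
    for (j in seq_along(va)) {
      sa <- valueShape(va[[j]]); sb <- valueShape(vb[[j]])
      if (sa != sb) {
        dfs <- rbind(dfs, newDifference("SubsectionType", paste0(section, "/", k),
          sprintf("%s value vs %s value", sa, sb)))
      } else if (!identical(va[[j]], vb[[j]])) {
        dfs <- rbind(dfs, newDifference("SubsectionValues", paste0(section, "/", k),
          "values differ"))
      }
    }
  }
  dfs
}

compareSSF <- function(a, b, dfs) {
  na <- length(a@records); nb <- length(b@records)
  if (na != nb)
    dfs <- rbind(dfs, newDifference("SSF", "SUBJECT_SAMPLE_FACTORS",
      sprintf("%d record(s) vs %d", na, nb)))
  for (i in seq_len(min(na, nb))) {
    ra <- a@records[[i]]; rb <- b@records[[i]]
    p <- sprintf("SUBJECT_SAMPLE_FACTORS[%d]", i)
    if (!identical(ra@subjectId, rb@subjectId))
      dfs <- rbind(dfs, newDifference("SSF", p, "subject IDs differ"))
    if (!identical(ra@sampleId, rb@sampleId))
      dfs <- rbind(dfs, newDifference("SSF", p, "sample IDs differ"))
    if (!dmEquivalent(ra@factors, rb@factors))
      dfs <- rbind(dfs, newDifference("SSF", p, "factors differ"))
    if (!dmEquivalent(ra@additionalData, rb@additionalData))
      dfs <- rbind(dfs, newDifference("SSF", p, "additional sample data differ"))
  }
  dfs
}

compareTables <- function(a, b, section, dfs) {
  if (!identical(a@role, b@role))
    dfs <- rbind(dfs, newDifference("DATA", section, "table roles differ"))
  ua <- if (length(a@units)) a@units[1] else ""
  ub <- if (length(b@units)) b@units[1] else ""
  if (!identical(ua, ub))
    dfs <- rbind(dfs, newDifference("DATA", paste0(section, "/Units"),
                                    "units differ"))
  if (!identical(a@columns, b@columns))
    dfs <- rbind(dfs, newDifference("DATA", paste0(section, "/columns"),
                                    "column names or order differ"))
  # The Factors preamble exists only in mwTab sources (and in this package's
  # own JSON); it is compared only when both documents carry one.
  if (length(a@factorsRow) && length(b@factorsRow) &&
      !identical(a@factorsRow, b@factorsRow))
    dfs <- rbind(dfs, newDifference("DATA", paste0(section, "/Factors"),
                                    "factor preamble rows differ"))
  na <- length(a@rows); nb <- length(b@rows)
  if (na != nb)
    dfs <- rbind(dfs, newDifference("DATA", section,
      sprintf("%d row(s) vs %d", na, nb)))
  for (i in seq_len(min(na, nb))) {
    ra <- a@rows[[i]]; rb <- b@rows[[i]]
    if (!identical(ra@keys, rb@keys)) {
      dfs <- rbind(dfs, newDifference("DATA", sprintf("%s[%d]", section, i),
                                      "row columns differ"))
    } else {
      va <- vapply(ra@values, cellText, character(1))
      vb <- vapply(rb@values, cellText, character(1))
      if (!identical(va, vb))
        dfs <- rbind(dfs, newDifference("DATA", sprintf("%s[%d]", section, i),
                                        "row values differ"))
    }
  }
  dfs
}

contentKind <- function(x) {
  if (is(x, "KeyValueBlock")) "key_value_block"
  else if (is(x, "SubjectSampleFactors")) "subject_sample_factors"
  else "data_table_composite"
}

#' Compare two parsed documents
#'
#' Structural equality comparison, typically between the mwTab-origin and
#' JSON-origin parses of one analysis. Every discrepancy is tagged with one
#' of six categories: `SectionKeys` (section present in one document only --
#' the bogus `#FACTORS` section is the classic case), `SubsectionKeys`,
#' `SubsectionValues`, `SubsectionType` (same subsection, different value
#' *shape*, e.g. scalar vs list), `DATA` (anything inside the DATA,
#' METABOLITES or EXTENDED tables) and `SSF` (anything inside the
#' SUBJECT_SAMPLE_FACTORS records). Row and column order inside tables is
#' significant; key/value blocks are compared with dictionary semantics.
#' An empty result means the documents are consistent.
#'
#' @param a,b [MWTabDocument-class] objects.
#' @return A data frame of differences (`category`, `path`, `detail`);
#'   zero rows iff consistent.
#' @export
compareDocuments <- function(a, b) {
  dfs <- noDifferences()
  na <- unique(a@sections@keys); nb <- unique(b@sections@keys)
  for (s in setdiff(na, nb))
    dfs <- rbind(dfs, newDifference("SectionKeys", s,
                                    "section present in first document only"))
  for (s in setdiff(nb, na))
    dfs <- rbind(dfs, newDifference("SectionKeys", s,
                                    "section present in second document only"))
  for (s in intersect(na, nb)) {
    ca <- getSection(a, s); cb <- getSection(b, s)
    if (contentKind(ca) != contentKind(cb)) {
      dfs <- rbind(dfs, newDifference("SectionKeys", s,
        sprintf("content kinds differ (%s vs %s)", contentKind(ca), contentKind(cb))))
      next
    }
    dfs <- if (is(ca, "KeyValueBlock")) compareBlocks(ca, cb, s, dfs)
           else if (is(ca, "SubjectSampleFactors")) compareSSF(ca, cb, dfs)
           else compareTables(ca, cb, s, dfs)
  }
  dfs[order(match(dfs$category, CONSISTENCY_CATEGORIES), dfs$path), ,
      drop = FALSE]
}

#' Tally consistency differences by category
#'
#' @param differences Data frame from [compareDocuments()] (possibly
#'   concatenated over many document pairs).
#' @return Named integer vector with one (possibly zero) count per category.
#' @export
summarizeDifferences <- function(differences) {
  counts <- table(factor(differences$category, levels = CONSISTENCY_CATEGORIES))
  stats::setNames(as.integer(counts), CONSISTENCY_CATEGORIES)
}

#' Are two documents consistent?
#'
#' @param a,b [MWTabDocument-class] objects.
#' @return `TRUE` iff [compareDocuments()] finds no differences.
#' @export
documentsConsistent <- function(a, b) nrow(compareDocuments(a, b)) == 0
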