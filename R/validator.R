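#' @include check-registry.R
NULL

# Metabolite name per row of a table (NA when the anchor column is absent
# or null valued).
metaboliteNames <- function(table) columnValues(table, CANONICAL_ANCHOR)

# Effective column set of a table: the header for harmonized (mwTab) tables,
# the union of row keys (first appearance order) for JSON tables.
tableColumns <- function(table) {
  if (length(table@columns)) return(table@columns)
  cols <- character(0)
  for (r in table@rows) for (k in r@keys) if (!k %in% cols) cols <- c(cols, k)
  cols
}

allTables <- function(doc) {
  idx <- which(vapply(doc@sections@values, is, logical(1), "MWTabTable"))
  stats::setNames(doc@sections@values[idx], doc@sections@keys[idx])
}

#' Checks on the SUBJECT_SAMPLE_FACTORS section (IDs 4--7)
#'
#' Duplicate sample IDs (4), duplicate factor keys within a record (5),
#' duplicate additional-data keys (6), and sample IDs used in the data table
#' that have no SUBJECT_SAMPLE_FACTORS record (7).
#'
#' @param doc A [MWTabDocument-class].
#' @return Validation message data frame.
#' @export
checkSubjectSampleFactors <- function(doc) {
  msgs <- emptyMessages()
  ssf <- ssfSection(doc)
  if (is.null(ssf)) return(msgs)
  ids <- vapply(ssf@records, function(r) r@sampleId, character(1))
  for (dup in unique(ids[duplicated(ids) & !isBlank(ids)]))
    msgs <- addMessage(msgs, 4, "SUBJECT_SAMPLE_FACTORS", dup,
      sprintf("Sample ID '%s' appears %d times", dup, sum(ids == dup)),
      occurrences = sum(ids == dup))
  tally <- function(getmap) {
    counts <- list()
    for (r in ssf@records) {
      k <- mapKeys(getmap(r))
      for (d in unique(k[duplicated(k)]))
        counts[[d]] <- (if (is.null(counts[[d]])) 0L else counts[[d]]) + 1L
    }
    counts
  }
  for (k in names(tally(function(r) r@factors)))
    msgs <- addMessage(msgs, 5, "SUBJECT_SAMPLE_FACTORS", k,
      sprintf("factor '%s' is repeated within a record", k))
  for (k in names(tally(function(r) r@additionalData)))
    msgs <- addMessage(msgs, 6, "SUBJECT_SAMPLE_FACTORS", k,
      sprintf("additional-data key '%s' is repeated within a record", k))
  dataTab <- findTable(doc, c("DATA", "NMR_BINNED"))
  if (!is.null(dataTab)) {
    samples <- setdiff(tableColumns(dataTab$table), CANONICAL_ANCHOR)
    missing <- setdiff(samples[!isBlank(samples)], ids)
    if (length(missing))
      msgs <- addMessage(msgs, 7, dataTab$name, CANONICAL_ANCHOR,
        sprintf("Sample ID(s) in the data table without a SUBJECT_SAMPLE_FACTORS record: %s",
                nameList(missing)),
        occurrences = length(missing))
  }
  msgs
}

#' Checks on the metabolite tables (IDs 8--14, 21--23, 32, 33, 35, 36)
#'
#' Set-difference checks between the DATA, METABOLITES and EXTENDED
#' metabolite and sample-ID sets; blank and duplicate metabolite names;
#' missing analytical (MS/NM) section; a data table without a METABOLITES
#' section; EXTENDED sample-ID coverage; and header-like metabolite names.
#'
#' @param doc A [MWTabDocument-class].
#' @return Validation message data frame.
#' @export
checkMetaboliteTables <- function(doc) {
  msgs <- emptyMessages()
  isJson <- sourceFormat(doc) == "json"
  dataTab <- findTable(doc, "DATA")
  metSec <- getSection(doc, "METABOLITES")
  met <- if (!is.null(metSec) && is(metSec, "MWTabTable")) metSec else NULL
  extTab <- findTable(doc, "EXTENDED")

  if (!isJson) {
    ann <- doc@annotations$duplicateSampleColumns
    for (i in seq_len(nrow(ann)))
      msgs <- addMessage(msgs, 8, ann$section[i], ann$column[i],
        sprintf("sample column '%s' appears more than once", ann$column[i]))
  }

  word <- function(x) if (isJson) x[2] else x[1]
  if (!is.null(dataTab)) {
    dn <- metaboliteNames(dataTab$table)
    blanks <- sum(isBlank(dn))
    if (blanks)
      msgs <- addMessage(msgs, 10, dataTab$name, CANONICAL_ANCHOR,
        sprintf("%d %s in the data table with a blank or null Metabolite name",
                blanks, word(c("row(s)", "object(s)"))), occurrences = blanks)
    dups <- unique(dn[duplicated(dn) & !isBlank(dn)])
    if (length(dups))
      msgs <- addMessage(msgs, 11, dataTab$name, CANONICAL_ANCHOR,
        sprintf("Metabolite name(s) repeated in the data table: %s", nameList(dups)),
        occurrences = length(dups))
    if (!is.null(met)) {
      mn <- metaboliteNames(met)
      only <- setdiff(unique(dn[!isBlank(dn)]), mn)
      if (length(only))
        msgs <- addMessage(msgs, 9, dataTab$name, CANONICAL_ANCHOR,
          sprintf("Metabolite(s) in the data table but not in METABOLITES: %s",
                  nameList(only)), occurrences = length(only))
    } else {
      msgs <- addMessage(msgs, 33, dataTab$name, "",
        sprintf("%s is present but the file has no METABOLITES %s",
                dataTab$name, word(c("section", "member"))))
    }
  }
  if (!is.null(met)) {
    mn <- metaboliteNames(met)
    blanks <- sum(isBlank(mn))
    if (blanks)
      msgs <- addMessage(msgs, 13, "METABOLITES", CANONICAL_ANCHOR,
        sprintf("%d row(s) in METABOLITES with a blank or null Metabolite name",
                blanks), occurrences = blanks)
    dups <- unique(mn[duplicated(mn) & !isBlank(mn)])
    if (length(dups))
      msgs <- addMessage(msgs, 14, "METABOLITES", CANONICAL_ANCHOR,
        sprintf("Metabolite name(s) repeated in METABOLITES: %s", nameList(dups)),
        occurrences = length(dups))
    if (!is.null(dataTab)) {
      dn <- metaboliteNames(dataTab$table)
      only <- setdiff(unique(mn[!isBlank(mn)]), dn)
      if (length(only))
        msgs <- addMessage(msgs, 12, "METABOLITES", CANONICAL_ANCHOR,
          sprintf("Metabolite(s) in METABOLITES but not in the data table: %s",
                  nameList(only)), occurrences = length(only))
    }
  }
  if (is.null(getSection(doc, "MS")) && is.null(getSection(doc, "NM")))
    msgs <- addMessage(msgs, 32, "", "",
      "the file has neither an MS nor an NM section; at least one is required")
  if (!is.null(extTab)) {
    ext <- extTab$table
    cols <- tableColumns(ext)
    if (!"sample_id" %in% cols) {
      msgs <- addMessage(msgs, 21, extTab$name, "sample_id",
        "the EXTENDED table is missing the required 'sample_id' column")
    } else {
      sv <- columnValues(ext, "sample_id")
      blanks <- sum(isBlank(sv))
      if (blanks)
        msgs <- addMessage(msgs, 35, extTab$name, "sample_id",
          sprintf("%d row(s) with a blank or null sample_id", blanks),
          occurrences = blanks)
      ssf <- ssfSection(doc)
      if (!is.null(ssf)) {
        ids <- vapply(ssf@records, function(r) r@sampleId, character(1))
        missing <- setdiff(ids[!isBlank(ids)], sv)
        if (length(missing))
          msgs <- addMessage(msgs, 22, extTab$name, "sample_id",
            sprintf("SUBJECT_SAMPLE_FACTORS Sample ID(s) with no EXTENDED entries: %s",
                    nameList(missing)), occurrences = length(missing))
      }
    }
    en <- metaboliteNames(ext)
    blanks <- sum(isBlank(en))
    if (blanks && CANONICAL_ANCHOR %in% cols)
      msgs <- addMessage(msgs, 36, extTab$name, CANONICAL_ANCHOR,
        sprintf("%d row(s) with a blank or null Metabolite name", blanks),
        occurrences = blanks)
  }
  headerLike <- c("metabolite_name", "metabolite", "metabolites", "compound",
                  "compound_name", "name", "metabolite_id", "samples",
                  "factors", "bin_range_ppm")
  for (tabName in names(allTables(doc))) {
    tab <- getSection(doc, tabName)
    if (!tab@role %in% c("DATA", "METABOLITES")) next
    nm <- metaboliteNames(tab)
    bad <- unique(nm[!is.na(nm) & normalizeColumnName(nm) %in% headerLike])
    if (length(bad))
      msgs <- addMessage(msgs, 23, tabName, CANONICAL_ANCHOR,
        sprintf("Metabolite name(s) that look like header text: %s", nameList(bad)),
        occurrences = length(bad))
  }
  msgs
}

#' Generic table checks (IDs 1, 2, 25--30, 34)
#'
#' Annotation-driven checks (duplicate subsections, header/row cell-count
#' mismatches, duplicate column names) plus per-table scans: inconsistent
#' per-row column sets, unnamed columns, all-null columns, near-constant
#' columns (the modal non-empty value covers at least 90% but not all of at
#' least 10 non-empty cells), duplicate rows and the required anchor header.
#'
#' @param doc A [MWTabDocument-class].
#' @return Validation message data frame.
#' @export
checkGenericTables <- function(doc) {
  msgs <- emptyMessages()
  isJson <- sourceFormat(doc) == "json"
  ann <- doc@annotations
  if (!isJson) {
    d <- ann$duplicateSubsections
    if (nrow(d)) {
      agg <- stats::aggregate(list(n = rep(1L, nrow(d))),
                              by = list(section = d$section, subsection = d$subsection),
                              FUN = sum)
      for (i in seq_len(nrow(agg)))
        msgs <- addMessage(msgs, 1, agg$section[i], agg$subsection[i],
          sprintf("subsection %s appears more than once in section %s",
                  agg$subsection[i], agg$section[i]), occurrences = agg$n[i])
    }
    h <- ann$headerMismatches
    for (s in unique(h$section)) {
      rows <- h[h$section == s, , drop = FALSE]
      msgs <- addMessage(msgs, 2, s, "",
        sprintf("%d row(s) with more data cells than header columns (e.g. row %d: %d cells for %d columns)",
                nrow(rows), rows$row[1], rows$observed[1], rows$expected[1]),
        occurrences = nrow(rows))
    }
    dcn <- ann$duplicateColumnNames
    for (i in seq_len(nrow(dcn)))
      msgs <- addMessage(msgs, 30, dcn$section[i], dcn$column[i],
        sprintf("column name '%s' appears more than once", dcn$column[i]))
  }
  tables <- allTables(doc)
  for (tabName in names(tables)) {
    tab <- tables[[tabName]]
    cols <- tableColumns(tab)
    if (length(tab@rows)) {
      refKeys <- tab@rows[[1]]@keys
      deviating <- sum(vapply(tab@rows, function(r) !identical(r@keys, refKeys),
                              logical(1)))
      if (deviating)
        msgs <- addMessage(msgs, 25, tabName, "",
          sprintf("%d %s with a different column set than the first",
                  deviating, if (isJson) "object(s)" else "row(s)"),
          occurrences = deviating)
    }
    unnamed <- sum(!nzchar(cols))
    if (unnamed)
      msgs <- addMessage(msgs, 26, tabName, "",
        sprintf("%d column(s) with no name", unnamed), occurrences = unnamed)
    if (length(tab@rows)) {
      for (col in unique(cols)) {
        vals <- columnValues(tab, col)
        nonEmpty <- vals[!isBlank(vals)]
        if (length(nonEmpty) == 0) {
          msgs <- addMessage(msgs, 27, tabName,
            if (nzchar(col)) col else "(unnamed)",
            sprintf("every value of column '%s' is null or blank", col))
        } else if (length(nonEmpty) >= 10) {
          share <- max(table(nonEmpty)) / length(nonEmpty)
          if (share >= 0.9 && share < 1)
            msgs <- addMessage(msgs, 28, tabName, col,
              sprintf("column '%s': %.0f%% of the non-empty values are identical; possibly a mistake",
                      col, 100 * share))
        }
      }
      sig <- vapply(tab@rows, function(r)
        paste(r@keys, vapply(r@values, cellText, character(1)),
              sep = "\r", collapse = "\n"), character(1))
      dupRows <- sum(duplicated(sig))
      if (dupRows)
        msgs <- addMessage(msgs, 29, tabName, "",
          sprintf("%d duplicated row(s)", dupRows), occurrences = dupRows)
    }
    if (tab@role %in% c("DATA", "METABOLITES")) {
      if (isJson) {
        if (!CANONICAL_ANCHOR %in% cols)
          msgs <- addMessage(msgs, 34, tabName, CANONICAL_ANCHOR,
            sprintf("table objects are missing the required '%s' key",
                    CANONICAL_ANCHOR))
      }
    }
  }
  if (!isJson) {
    am <- ann$anchorMismatches
    for (i in seq_len(nrow(am)))
      msgs <- addMessage(msgs, 34, am$section[i], CANONICAL_ANCHOR,
        sprintf("table header names its anchor column '%s' instead of the required '%s'",
                am$observed[i], CANONICAL_ANCHOR))
  }
  msgs
}

#' Standard-column checks on the METABOLITES table (IDs 15--20, 31)
#'
#' Rename candidates (15, always a warning), bad standard values (16),
#' missing implied partner columns (17), row-wise partner value mismatches
#' (18), presence of the discouraged `other_id` column (19), names matching
#' more than one standard column (20) and mixed polarity values (31).
#'
#' @param doc A [MWTabDocument-class].
#' @param registry Column-finder registry; see [defaultColumnRegistry()].
#' @return Validation message data frame.
#' @export
checkStandardColumns <- function(doc, registry = defaultColumnRegistry()) {
  msgs <- emptyMessages()
  metSec <- getSection(doc, "METABOLITES")
  if (is.null(metSec) || !is(metSec, "MWTabTable")) return(msgs)
  met <- metSec
  cols <- tableColumns(met)
  outcomes <- findStandardColumns(cols, registry)
  canonicalOf <- list()   # canonical -> first raw column matching it uniquely
  for (o in outcomes) {
    if (length(o$matches) > 1) {
      msgs <- addMessage(msgs, 20, "METABOLITES", o$raw,
        sprintf("column '%s' matches several standard names (%s); it is likely pulling double duty",
                o$raw, paste(o$matches, collapse = ", ")))
      next
    }
    if (length(o$matches) == 0) next
    canonical <- o$matches
    if (o$renameCandidate)
      msgs <- addMessage(msgs, 15, "METABOLITES", o$raw,
        sprintf("column '%s' looks like the standard column '%s' and should be renamed",
                o$raw, canonical))
    if (is.null(canonicalOf[[canonical]])) canonicalOf[[canonical]] <- o$raw
    bad <- validateColumnValues(canonical, columnValues(met, o$raw), registry)
    if (length(bad))
      msgs <- addMessage(msgs, 16, "METABOLITES", o$raw,
        sprintf("%d value(s) in column '%s' do not look like %s values (e.g. row %d)",
                length(bad), o$raw, canonical, bad[1]),
        occurrences = length(bad))
    if (canonical == "other_id")
      msgs <- addMessage(msgs, 19, "METABOLITES", o$raw,
        "an 'other_id' column is present; prefer a specific identifier column such as 'kegg_id' or 'lab_id'")
    if (canonical == "polarity") {
      vals <- columnValues(met, o$raw)
      distinct <- unique(toupper(trimws(vals[!isBlank(vals)])))
      if (length(distinct) > 1)
        msgs <- addMessage(msgs, 31, "METABOLITES", o$raw,
          sprintf("polarity column '%s' mixes values (%s); one analysis should be a single polarity",
                  o$raw, nameList(distinct)))
    }
  }
  present <- names(canonicalOf)
  for (canonical in present) {
    partners <- registry[[canonical]]@impliedPartners
    for (p in setdiff(partners, present))
      msgs <- addMessage(msgs, 17, "METABOLITES", canonicalOf[[canonical]],
        sprintf("column '%s' (%s) implies a '%s' column, which is not present",
                canonicalOf[[canonical]], canonical, p))
    for (p in intersect(partners, present)) {
      va <- columnValues(met, canonicalOf[[canonical]])
      vb <- columnValues(met, canonicalOf[[p]])
      mism <- which(isBlank(va) != isBlank(vb))
      if (length(mism) && canonical < p)
        msgs <- addMessage(msgs, 18, "METABOLITES", canonicalOf[[canonical]],
          sprintf("columns '%s' and '%s' are paired but %d row(s) have a value in only one (e.g. row %d)",
                  canonicalOf[[canonical]], canonicalOf[[p]], length(mism), mism[1]),
          occurrences = length(mism))
    }
  }
  msgs
}

# Tolerant factor-string parse for comparison purposes: key:value pairs
# joined by |; fragments that do not split cleanly compare as raw text.
factorPairsForCompare <- function(text) {
  frags <- trimws(strsplit(text, "|", fixed = TRUE)[[1]])
  frags <- frags[nzchar(frags)]
  sort(vapply(frags, function(f) {
    m <- regmatches(f, regexec("^([^:]*):(.*)$", f))[[1]]
    if (length(m) == 3) paste0(trimws(m[2]), ":", trimws(m[3])) else f
  }, character(1), USE.NAMES = FALSE))
}

#' Factor agreement between the data table and SUBJECT_SAMPLE_FACTORS (ID 3)
#'
#' mwTab flat text carries the factors twice: once per
#' SUBJECT_SAMPLE_FACTORS record and once in the data table's `Factors`
#' preamble row. This check compares them per sample; it is inapplicable to
#' JSON-origin documents, which have no second factor source.
#'
#' @param doc A [MWTabDocument-class].
#' @return Validation message data frame.
#' @export
checkFactorMatch <- function(doc) {
  msgs <- emptyMessages()
  if (sourceFormat(doc) == "json") return(msgs)
  dataTab <- findTable(doc, c("DATA", "NMR_BINNED"))
  ssf <- ssfSection(doc)
  if (is.null(dataTab) || is.null(ssf)) return(msgs)
  tab <- dataTab$table
  if (length(tab@factorsRow) == 0) return(msgs)
  samples <- setdiff(tab@columns, CANONICAL_ANCHOR)
  ssfBySample <- list()
  for (r in ssf@records)
    if (is.null(ssfBySample[[r@sampleId]])) ssfBySample[[r@sampleId]] <- r
  bad <- character(0)
  for (i in seq_along(samples)) {
    rec <- ssfBySample[[samples[i]]]
    if (is.null(rec)) next   # missing records are ID 7's concern
    tf <- if (i <= length(tab@factorsRow)) tab@factorsRow[i] else ""
    if (!identical(factorPairsForCompare(tf),
                   factorPairsForCompare(serializeFactors(rec@factors))))
      bad <- c(bad, samples[i])
  }
  if (length(bad))
    msgs <- addMessage(msgs, 3, dataTab$name, "Factors",
      sprintf("factors in the data table and SUBJECT_SAMPLE_FACTORS disagree for sample(s): %s",
              nameList(bad)), occurrences = length(bad))
  msgs
}

#' Run the full validation suite on a document
#'
#' Runs the 36-check suite plus structural schema validation, producing a
#' deterministic, condensed message list: one message per (check, section,
#' subsection-or-column) root cause with an occurrence count, worded for the
#' document's source format. Never raises on a parsable document; an
#' internal failure inside one check group is itself reported as a message.
#'
#' @param doc A [MWTabDocument-class].
#' @param registry Column-finder registry; see [defaultColumnRegistry()].
#' @param schemaRules Schema rule table; see [defaultSchemaRules()].
#' @return Data frame of validation messages: `id`, `short_name`,
#'   `severity`, `categories`, `section`, `subsection`, `message`,
#'   `occurrences`. Zero rows means the document is Passing.
#' @seealso [categorizeMessages()], [checkRegistry()]
#' @export
validateDocument <- function(doc, registry = defaultColumnRegistry(),
                             schemaRules = defaultSchemaRules()) {
  stopifnot(is(doc, "MWTabDocument"))
  groups <- list(
    function() checkGenericTables(doc),
    function() checkSubjectSampleFactors(doc),
    function() checkMetaboliteTables(doc),
    function() checkStandardColumns(doc, registry),
    function() checkFactorMatch(doc),
    function() validateStructure(doc, schemaRules))
  msgs <- emptyMessages()
  for (g in groups) {
    part <- tryCatch(g(), error = function(e)
      addMessage(emptyMessages(), NA_integer_, "", "",
                 paste("internal check failure:", conditionMessage(e)),
                 categories = "format", severity = "error"))
    msgs <- rbind(msgs, part)
  }
  # only checks applicable to this source format
  reg <- getCheckRegistry()
  applicable <- reg$id[reg$applicability %in% c("both", sourceFormat(doc))]
  msgs <- msgs[is.na(msgs$id) | msgs$id %in% applicable, , drop = FALSE]
  msgs <- msgs[order(msgs$id, msgs$section, msgs$subsection, msgs$message), ,
               drop = FALSE]
  rownames(msgs) <- NULL
  msgs
}

#' Classify a validation message list into a file status
#'
#' `Passing` -- no messages; `Warnings Only` -- every message is a warning;
#' `Errors` -- at least one non-warning message. The category flags are true
#' iff a non-warning message carries that tag.
#'
#' @param messages Data frame from [validateDocument()].
#' @return List with `status` (`"Passing"`, `"Warnings Only"` or
#'   `"Errors"`), `hasConsistencyErrors`, `hasValueErrors`,
#'   `hasFormatErrors` and `messageCount`.
#' @export
categorizeMessages <- function(messages) {
  n <- nrow(messages)
  status <- if (n == 0) "Passing"
            else if (all(messages$severity == "warning")) "Warnings Only"
            else "Errors"
  err <- messages[messages$severity != "warning", , drop = FALSE]
  list(status = status,
       hasConsistencyErrors = any(messageHasCategory(err, "consistency")),
       hasValueErrors = any(messageHasCategory(err, "value")),
       hasFormatErrors = any(messageHasCategory(err, "format")),
       messageCount = n)
}
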