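#' @include read-mwtab.R
NULL

# Sections in the predefined write-out order, then any out-of-vocabulary
# sections in encounter order; byte-deterministic for a given document.
orderedSectionNames <- function(doc) {
  present <- doc@sections@keys
  known <- CANONICAL_SECTION_ORDER[CANONICAL_SECTION_ORDER %in% present]
  c(known, present[!present %in% CANONICAL_SECTION_ORDER])
}

serializeFactors <- function(dm) {
  if (length(dm@keys) == 0) return("")
  paste(paste0(dm@keys, ":",
               vapply(dm@values, function(v) as.character(v)[1], character(1))),
        collapse = " | ")
}

serializeAdditional <- function(dm) {
  if (length(dm@keys) == 0) return("")
  paste(paste0(dm@keys, "=",
               vapply(dm@values, function(v) as.character(v)[1], character(1))),
        collapse = "; ")
}

cellText <- function(v) {
  if (is.null(v) || length(v) == 0 || is.na(v[1])) "" else as.character(v)[1]
}

# One data row in stored column order. Rows are harmonized, so the keys are
# the header's columns; values are emitted in stored order.
serializeTableRow <- function(row) {
  paste(vapply(row@values, cellText, character(1)), collapse = "\t")
}

writeSectionLines <- function(name, content, out) {
  prefix <- SECTION_PREFIX[name]
  if (name == HEADER_SECTION) {
    items <- content@items
    headKeys <- c("STUDY_ID", "ANALYSIS_ID", "PROJECT_ID")
    headKeys <- headKeys[headKeys %in% items@keys]
    headParts <- vapply(headKeys, function(k)
      paste0(k, ":", cellText(mapGet(items, k)[[1]])), character(1))
    out(paste(c(paste0("#", HEADER_SECTION), headParts), collapse = " "))
    for (i in seq_along(items@keys)) {
      if (items@keys[i] %in% headKeys) next
      out(paste0(items@keys[i], "\t", cellText(items@values[[i]])))
    }
    return(invisible())
  }
  out(paste0("#", name))
  if (is(content, "KeyValueBlock")) {
    items <- content@items
    for (i in seq_along(items@keys)) {
      v <- items@values[[i]]
      vals <- if (is.list(v)) vapply(v, cellText, character(1)) else cellText(v)
      for (vv in vals) {
        lead <- if (is.na(prefix)) items@keys[i]
                else paste0(prefix, ":", items@keys[i])
        out(paste0(lead, "\t", vv))
      }
    }
  } else if (is(content, "SubjectSampleFactors")) {
    for (rec in content@records) {
      out(paste("SUBJECT_SAMPLE_FACTORS", rec@subjectId, rec@sampleId,
                serializeFactors(rec@factors),
                serializeAdditional(rec@additionalData), sep = "\t"))
    }
  } else if (is(content, "MWTabTable")) {
    tab <- content
    if (length(tab@units))
      out(paste0(name, ":UNITS\t", tab@units[1]))
    out(paste0(name, "_START"))
    if (isPreambleTable(tab@role)) {
      samples <- if (length(tab@columns)) tab@columns[-1] else character(0)
      out(paste(c("Samples", samples), collapse = "\t"))
      if (length(tab@factorsRow))
        out(paste(c("Factors", tab@factorsRow), collapse = "\t"))
    } else {
      out(paste(tab@columns, collapse = "\t"))
    }
    for (row in tab@rows) out(serializeTableRow(row))
    out(paste0(name, "_END"))
  }
  invisible()
}

#' Serialize a document to mwTab flat text
#'
#' Sections and subsections are emitted in the canonical, predefined order
#' so that writing the same document twice yields identical bytes.
#' `parseMWTab(formatMWTab(doc))` reproduces the document's content.
#'
#' @param doc A [MWTabDocument-class].
#' @return A single UTF-8 string (newline-terminated lines, trailing `#END`).
#' @export
formatMWTab <- function(doc) {
  lines <- character(0)
  out <- function(x) lines[[length(lines) + 1]] <<- x
  for (name in orderedSectionNames(doc)) {
    idx <- which(doc@sections@keys == name)
    for (i in idx) writeSectionLines(name, doc@sections@values[[i]], out)
  }
  out("#END")
  paste0(paste(lines, collapse = "\n"), "\n")
}

#' Write a document as an mwTab flat-text file
#'
#' Missing output directories are created rather than treated as fatal.
#'
#' @param doc A [MWTabDocument-class].
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
writeMWTab <- function(doc, path) {
  writeFileUTF8(formatMWTab(doc), path)
}

writeFileUTF8 <- function(text, path) {
  dir <- dirname(path)
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  con <- file(path, open = "wb")
  on.exit(close(con))
  writeBin(charToRaw(enc2utf8(text)), con)
  invisible(path)
}
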