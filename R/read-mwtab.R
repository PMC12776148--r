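#' @include tokenizer.R
NULL

CANONICAL_ANCHOR <- "Metabolite"

tableRoleForSection <- function(section) {
  switch(section,
         "MS_METABOLITE_DATA" = "DATA",
         "NMR_METABOLITE_DATA" = "DATA",
         "NMR_BINNED_DATA" = "NMR_BINNED",
         "METABOLITES" = "METABOLITES",
         "EXTENDED_MS_METABOLITE_DATA" = "EXTENDED",
         "EXTENDED_NMR_METABOLITE_DATA" = "EXTENDED",
         NA_character_)
}

# DATA-style tables open with a Samples (+ optional Factors) preamble and
# carry no literal header row; METABOLITES/EXTENDED tables open with a
# literal header row whose anchor column is canonicalized to "Metabolite".
isPreambleTable <- function(role) role %in% c("DATA", "NMR_BINNED")

#' Parse mwTab flat text into a document
#'
#' @param text Full file text (single string or character vector of lines).
#' @return A [MWTabDocument-class] with `sourceFormat = "mwtab"` and parse
#'   annotations populated.
#' @seealso [readMWTab()] for reading from a file path.
#' @export
parseMWTab <- function(text) {
  lexed <- tokenizeMWTab(text)
  ann <- emptyAnnotations()
  ann$bogusSectionLines <- lexed$bogusSectionLines

  sections <- DuplicatesMap()
  curName <- NULL
  curItems <- NULL          # DuplicatesMap for key/value sections
  curSSF <- NULL            # list of SSFRecord
  curUnits <- character(0)
  tableRows <- NULL         # raw cell rows of the open/last table
  pendingTables <- list()   # finished tables awaiting section close

  finishTable <- function(section, cellRows) {
    role <- tableRoleForSection(section)
    if (is.na(role)) role <- "METABOLITES"  # unknown fenced table: header-style
    factorsRow <- character(0)
    if (isPreambleTable(role)) {
      samples <- character(0)
      dataRows <- list()
      for (cells in cellRows) {
        first <- if (length(cells)) cells[1] else ""
        if (first == "Samples" && length(samples) == 0) {
          samples <- cells[-1]
        } else if (first == "Factors" && length(factorsRow) == 0) {
          factorsRow <- cells[-1]
        } else {
          dataRows[[length(dataRows) + 1]] <- cells
        }
      }
      header <- c(CANONICAL_ANCHOR, samples)
      if (length(factorsRow)) {
        h <- harmonizeRow(samples, factorsRow)
        factorsRow <- h$cells
      }
      dup <- samples[duplicated(samples)]
      if (length(dup))
        ann$duplicateSampleColumns <<- rbind(
          ann$duplicateSampleColumns,
          data.frame(section = section, column = unique(dup), stringsAsFactors = FALSE))
    } else {
      if (length(cellRows) == 0) {
        header <- character(0)
        dataRows <- list()
      } else {
        header <- cellRows[[1]]
        if (length(header) && !identical(header[1], CANONICAL_ANCHOR)) {
          # The table is always built with the canonical anchor name; the
          # literal text is an annotation, not data.
          ann$anchorMismatches <<- rbind(
            ann$anchorMismatches,
            data.frame(section = section, observed = header[1],
                       stringsAsFactors = FALSE))
          header[1] <- CANONICAL_ANCHOR
        }
        dataRows <- cellRows[-1]
        dup <- header[duplicated(header)]
        if (length(dup))
          ann$duplicateColumnNames <<- rbind(
            ann$duplicateColumnNames,
            data.frame(section = section, column = unique(dup),
                       stringsAsFactors = FALSE))
      }
    }
    rows <- vector("list", length(dataRows))
    for (j in seq_along(dataRows)) {
      h <- harmonizeRow(header, dataRows[[j]])
      if (!is.null(h$mismatch))
        ann$headerMismatches <<- rbind(
          ann$headerMismatches,
          data.frame(section = section, row = j, observed = h$mismatch,
                     expected = length(header), stringsAsFactors = FALSE))
      rows[[j]] <- DuplicatesMap(header, as.list(h$cells))
    }
    MWTabTable(role = role, units = curUnits, columns = header,
               factorsRow = factorsRow, rows = rows)
  }

  closeSection <- function() {
    if (is.null(curName)) return(invisible())
    content <- if (!is.null(curSSF)) {
      SubjectSampleFactors(records = curSSF)
    } else if (length(pendingTables)) {
      pendingTables[[1]]
    } else {
      items <- if (is.null(curItems)) DuplicatesMap() else curItems
      KeyValueBlock(items = items)
    }
    sections <<- mapAppend(sections, curName, content)
    curName <<- NULL; curItems <<- NULL; curSSF <<- NULL
    curUnits <<- character(0); pendingTables <<- list()
  }

  inTable <- FALSE
  for (tok in lexed$tokens) {
    switch(tok$kind,
      SectionHeader = {
        closeSection()
        curName <- tok$name
        curItems <- DuplicatesMap()
        if (curName == "SUBJECT_SAMPLE_FACTORS") curSSF <- list()
        for (it in tok$items) curItems <- mapAppend(curItems, it$key, it$value)
      },
      EndMarker = closeSection(),
      Item = {
        if (is.null(curName))
          parseError("item line before any section header", tok$lineNo,
                     "mwtab_parse_error_orphan_line")
        key <- tok$key
        if (key == "UNITS" && !is.na(tableRoleForSection(curName))) {
          curUnits <- tok$value
        } else {
          if (mapHas(curItems, key))
            ann$duplicateSubsections <- rbind(
              ann$duplicateSubsections,
              data.frame(section = curName, subsection = key, stringsAsFactors = FALSE))
          curItems <- mapAppend(curItems, key, tok$value)
        }
      },
      SSFLine = {
        if (is.null(curSSF)) curSSF <- list()
        if (is.null(curName)) curName <- "SUBJECT_SAMPLE_FACTORS"
        raw <- paste(tok$cells, collapse = "\t")
        curSSF[[length(curSSF) + 1]] <-
          parseSSFLine(tok$cells, tok$lineNo, rawLine = raw)
      },
      TableBegin = { inTable <- TRUE; tableRows <- list() },
      TableRow = { tableRows[[length(tableRows) + 1]] <- tok$cells },
      TableEnd = {
        inTable <- FALSE
        if (is.null(curName))
          parseError("table outside any section", tok$lineNo,
                     "mwtab_parse_error_table_fence")
        pendingTables[[length(pendingTables) + 1]] <- finishTable(curName, tableRows)
        tableRows <- NULL
      },
      Blank = NULL)
  }
  closeSection()
  MWTabDocument(sections = sections, sourceFormat = "mwtab", annotations = ann)
}

#' Read an mwTab flat-text file
#'
#' @param path Path to a UTF-8 mwTab file.
#' @return A [MWTabDocument-class]; see [parseMWTab()].
#' @export
readMWTab <- function(path) {
  text <- readFileUTF8(path)
  withCallingHandlers(
    parseMWTab(text),
    error = function(e) {
      if (inherits(e, "mwtab_parse_error") && is.null(attr(e, "mwtab_file"))) {
        e$message <- sprintf("%s: %s", path, conditionMessage(e))
        attr(e, "mwtab_file") <- path
        stop(e)
      }
    })
}

# Strict UTF-8 read; undecodable bytes are an error, not silently mangled.
readFileUTF8 <- function(path) {
  if (!is.character(path) || !file.exists(path))
    parseError(sprintf("cannot open '%s': no such file", path),
               class = "mwtab_parse_error_io")
  raw <- readBin(path, "raw", n = file.size(path))
  txt <- rawToChar(raw)
  Encoding(txt) <- "UTF-8"
  if (!validUTF8(txt))
    parseError(sprintf("%s is not valid UTF-8", path), class = "mwtab_parse_error_encoding")
  gsub("\r\n", "\n", txt, fixed = TRUE)
}
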