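#' @include MWTabDocument-methods.R
NULL

# Parse errors are classed conditions so callers (and the batch machinery)
# can distinguish defect classes.
parseError <- function(message, lineNo = NA_integer_, class = NULL) {
  stop(structure(
    class = c(class, "mwtab_parse_error", "error", "condition"),
    list(message = if (is.na(lineNo)) message
         else sprintf("line %d: %s", lineNo, message),
         call = NULL, lineNo = lineNo)))
}

#' Classify one physical line of an mwTab file
#'
#' Every non-blank line maps to exactly one token or raises a classed parse
#' error carrying its 1-based line number. Tokens are lists with a `kind`
#' field (`SectionHeader`, `Item`, `SSFLine`, `TableBegin`, `TableEnd`,
#' `TableRow`, `Blank`) plus kind-specific fields.
#'
#' Two refusal classes mirror defects observed in real depositions: a line
#' with a section-code prefix but no tab separator (`missing tab`), and an
#' uncapitalized, prefix-less line outside a table -- the footprint of a
#' value containing an embedded carriage return (`orphan line`).
#'
#' @param line One physical line (no trailing newline).
#' @param lineNo 1-based line number, reported in errors.
#' @param inTable Is the line inside a fenced table? Tab-delimited rows are
#'   then returned as `TableRow` tokens.
#' @return A token (named list).
#' @export
classifyLine <- function(line, lineNo = NA_integer_, inTable = FALSE) {
  if (grepl("\r", line, fixed = TRUE))
    parseError("embedded carriage return in line", lineNo, "mwtab_parse_error_orphan_line")
  if (!nzchar(trimws(line)))
    return(list(kind = "Blank", lineNo = lineNo))
  if (startsWith(line, "#")) {
    body <- trimws(substring(line, 2))
    if (identical(body, "END"))
      return(list(kind = "EndMarker", lineNo = lineNo))
    # "#METABOLOMICS WORKBENCH STUDY_ID:STxxxxxx ..." carries header items.
    name <- body
    items <- list()
    if (startsWith(body, HEADER_SECTION)) {
      name <- HEADER_SECTION
      rest <- trimws(substring(body, nchar(HEADER_SECTION) + 1))
      if (nzchar(rest)) {
        for (tokstr in strsplit(rest, "[ \t]+")[[1]]) {
          m <- regmatches(tokstr, regexec("^([A-Z][A-Z0-9_]*):(.*)$", tokstr))[[1]]
          if (length(m) == 3) items[[length(items) + 1]] <- list(key = m[2], value = m[3])
        }
      }
    }
    return(list(kind = "SectionHeader", name = name, items = items, lineNo = lineNo))
  }
  if (grepl("^[A-Z][A-Z0-9_ ]*_(START|END)$", line)) {
    kind <- if (endsWith(line, "_START")) "TableBegin" else "TableEnd"
    fence <- sub("_(START|END)$", "", line)
    return(list(kind = kind, fence = fence, lineNo = lineNo))
  }
  if (inTable) {
    return(list(kind = "TableRow", cells = strsplit(line, "\t", fixed = TRUE)[[1]],
                lineNo = lineNo))
  }
  if (startsWith(line, "SUBJECT_SAMPLE_FACTORS\t")) {
    return(list(kind = "SSFLine", cells = strsplit(line, "\t", fixed = TRUE)[[1]],
                lineNo = lineNo))
  }
  m <- regmatches(line, regexec("^([A-Z][A-Z0-9_]*):([^\t]*)\t(.*)$", line))[[1]]
  if (length(m) == 4)
    return(list(kind = "Item", prefix = m[2], key = m[3], value = m[4], lineNo = lineNo))
  if (grepl("^[A-Z][A-Z0-9_]*:[^\t]*$", line))
    parseError(sprintf("missing tab after section code in '%s'",
                       substr(line, 1, 40)),
               lineNo, "mwtab_parse_error_missing_tab")
  m <- regmatches(line, regexec("^([A-Z][A-Z0-9_]*)\t(.*)$", line))[[1]]
  if (length(m) == 3)
    return(list(kind = "Item", prefix = NA_character_, key = m[2], value = m[3],
                lineNo = lineNo))
  parseError(sprintf("orphan line (no capitalized section code): '%s'",
                     substr(line, 1, 40)),
             lineNo, "mwtab_parse_error_orphan_line")
}

# Split a factors/additional-data fragment string into a DuplicatesMap,
# refusing genuinely ambiguous key/value splits.
parseDelimitedPairs <- function(text, pairSep, kvSep, what, lineNo) {
  out <- DuplicatesMap()
  text <- trimws(text)
  if (!nzchar(text) || text == "-") return(out)
  frags <- strsplit(text, pairSep, fixed = TRUE)[[1]]
  for (frag in frags) {
    frag <- trimws(frag)
    if (!nzchar(frag)) next
    nsep <- lengths(regmatches(frag, gregexpr(kvSep, frag, fixed = TRUE)))
    if (nsep != 1)
      parseError(sprintf(
        "%s fragment '%s' has %d '%s' separators (exactly one expected); %s",
        what, frag, nsep, kvSep,
        if (nsep == 0) sprintf("a '%s' delimiter between pairs may be missing", pairSep)
        else sprintf("an extra '%s' makes the key/value split ambiguous", kvSep)),
        lineNo, "mwtab_parse_error_ssf")
    kv <- regmatches(frag, regexec(paste0("^([^", kvSep, "]*)", kvSep, "(.*)$"),
                                   frag))[[1]]
    out <- mapAppend(out, trimws(kv[2]), trimws(kv[3]))
  }
  out
}

#' Parse the tab-split cells of one SUBJECT_SAMPLE_FACTORS line
#'
#' Fields are `SUBJECT_SAMPLE_FACTORS`, subject ID, sample ID, factors
#' (`key:value` pairs joined by `|`) and additional data (`key=value` pairs
#' joined by `;`). Unambiguous extra whitespace is tolerated; a fragment with
#' zero or two-plus separators (a missing `;`, an extra `=` or an extra `:`)
#' is refused rather than guessed at, since a wrong guess silently corrupts
#' the record.
#'
#' @param cells Character vector of the tab-split fields (including the
#'   leading `SUBJECT_SAMPLE_FACTORS` cell).
#' @param lineNo 1-based source line number for error reporting.
#' @param rawLine Optional raw line retained on the record.
#' @return An [SSFRecord-class].
#' @export
parseSSFLine <- function(cells, lineNo = NA_integer_, rawLine = character(0)) {
  cells <- c(cells, rep("", max(0, 5 - length(cells))))
  SSFRecord(
    subjectId = cells[2], sampleId = cells[3],
    factors = parseDelimitedPairs(cells[4], "|", ":", "factors", lineNo),
    additionalData = parseDelimitedPairs(cells[5], ";", "=", "additional data", lineNo),
    rawLine = rawLine)
}

#' Harmonize one table row against its header
#'
#' Real depositions show two tab defects: extra tabs with no data tacked on
#' to the end of rows, and missing tabs when the last column(s) are blank.
#' Harmonization drops trailing empty overflow cells, pads short rows with
#' empty text, and records (never rejects) rows whose non-empty cells
#' genuinely overflow the header -- that fact feeds the bad-headers
#' validation. The result always has exactly `length(header)` cells and the
#' operation is idempotent.
#'
#' @param header Character vector: the table's header row.
#' @param cells Character vector: one data row's tab-split cells.
#' @return List with `cells` (length `length(header)`) and `mismatch`
#'   (`NULL`, or the observed cell count when non-empty cells overflowed).
#' @export
harmonizeRow <- function(header, cells) {
  n <- length(header)
  mismatch <- NULL
  if (length(cells) > n) {
    overflow <- cells[(n + 1):length(cells)]
    if (any(nzchar(overflow))) mismatch <- length(cells)
    while (length(cells) > n && !nzchar(cells[length(cells)]))
      cells <- cells[-length(cells)]
    if (length(cells) > n) cells <- cells[seq_len(n)]
  } else if (length(cells) < n) {
    cells <- c(cells, rep("", n - length(cells)))
  }
  list(cells = cells, mismatch = mismatch)
}

#' Tokenize full mwTab text
#'
#' Lexes the file into a token stream in file order, managing table-fence
#' context. A repeated `*_DATA_END` fence with rows between (one known,
#' badly mangled deposition class) is refused; a `#FACTORS` (or any
#' out-of-vocabulary) section header is tokenized and its line number
#' recorded in the `bogusSectionLines` annotation rather than dropped.
#'
#' @param text Full file text (single string, or character vector of lines).
#' @return List with `tokens` and `bogusSectionLines` (line numbers of
#'   out-of-vocabulary section headers; the remaining annotations are
#'   recorded while building the document).
#' @export
tokenizeMWTab <- function(text) {
  lines <- if (length(text) == 1) strsplit(text, "\n", fixed = TRUE)[[1]] else text
  tokens <- vector("list", length(lines))
  ntok <- 0
  bogus <- integer(0)
  inTable <- FALSE
  fence <- NULL
  lastFence <- NULL     # fence of a table that just closed (limbo state)
  pendingRow <- NA_integer_  # first row-like line seen after a table closed
  flushPending <- function(i) {
    if (!is.na(pendingRow))
      parseError("orphan line after table end", pendingRow,
                 "mwtab_parse_error_orphan_line")
  }
  for (i in seq_along(lines)) {
    # While in post-table limbo, row-like lines are held back: they are the
    # signature of a table wrongly split by multiple *_END fences.
    tok <- classifyLine(lines[i], i, inTable = inTable || !is.null(lastFence))
    if (tok$kind == "TableBegin") {
      flushPending(i)
      if (inTable)
        parseError(sprintf("nested %s_START inside open table", tok$fence),
                   i, "mwtab_parse_error_table_fence")
      inTable <- TRUE
      fence <- tok$fence
      lastFence <- NULL
    } else if (tok$kind == "TableEnd") {
      if (!inTable) {
        if (identical(tok$fence, lastFence))
          parseError(sprintf("multiple %s_END lines between table rows", tok$fence),
                     i, "mwtab_parse_error_multiple_data_end")
        flushPending(i)
        parseError(sprintf("%s_END without matching start", tok$fence),
                   i, "mwtab_parse_error_table_fence")
      }
      if (!identical(tok$fence, fence))
        parseError(sprintf("%s_END closes %s_START", tok$fence, fence),
                   i, "mwtab_parse_error_table_fence")
      inTable <- FALSE
      lastFence <- fence
      pendingRow <- NA_integer_
      fence <- NULL
    } else if (tok$kind %in% c("SectionHeader", "EndMarker")) {
      flushPending(i)
      lastFence <- NULL
      if (tok$kind == "SectionHeader" && !tok$name %in% KNOWN_SECTIONS)
        bogus <- c(bogus, i)
    } else if (tok$kind == "TableRow" && !inTable) {
      if (is.na(pendingRow)) pendingRow <- i
      next
    } else if (tok$kind %in% c("Item", "SSFLine")) {
      lastFence <- NULL
    }
    ntok <- ntok + 1
    tokens[[ntok]] <- tok
  }
  flushPending(length(lines) + 1)
  if (inTable)
    parseError(sprintf("%s_START never closed", fence),
               length(lines), "mwtab_parse_error_table_fence")
  list(tokens = tokens[seq_len(ntok)], bogusSectionLines = bogus)
}
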