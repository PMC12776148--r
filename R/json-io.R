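#' @include write-mwtab.R
NULL

TABLE_COMPOSITE_SECTIONS <- c("MS_METABOLITE_DATA", "NMR_METABOLITE_DATA",
                              "NMR_BINNED_DATA")

# ---- reading ---------------------------------------------------------------

jsonScalarToText <- function(v) {
  if (is.null(v)) NULL else as.character(v)[1]
}

jsonRowToMap <- function(row) {
  dm <- DuplicatesMap()
  keys <- names(row)
  if (is.null(keys)) keys <- rep("", length(row))
  for (i in seq_along(row))
    dm <- mapAppend(dm, keys[i], jsonScalarToText(row[[i]]))
  dm
}

jsonObjectToBlock <- function(obj) {
  dm <- DuplicatesMap()
  keys <- names(obj)
  for (i in seq_along(obj)) {
    v <- obj[[i]]
    val <- if (is.null(v)) NULL
           else if (is.list(v)) lapply(v, jsonScalarToText)
           else as.character(v)[1]
    dm <- mapAppend(dm, keys[i], val)
  }
  KeyValueBlock(items = dm)
}

jsonRowsToTable <- function(rowList, role, sectionName, force, units = character(0),
                            factors = NULL) {
  rows <- list()
  columns <- character(0)
  for (i in seq_along(rowList)) {
    r <- rowList[[i]]
    if (!is.list(r) || is.null(names(r))) {
      if (!force)
        parseError(sprintf(
          "row %d of %s is not an object (value: %s); re-run with force = TRUE to skip such rows",
          i, sectionName, deparse(unlist(r))[1]),
          class = "mwtab_parse_error_json_false_row")
      warning(sprintf("skipping non-object row %d of %s (force)", i, sectionName),
              call. = FALSE)
      next
    }
    dm <- jsonRowToMap(r)
    for (k in dm@keys) if (!k %in% columns) columns <- c(columns, k)
    rows[[length(rows) + 1]] <- dm
  }
  factorsRow <- character(0)
  if (!is.null(factors) && length(factors)) {
    nonAnchor <- columns[columns != CANONICAL_ANCHOR]
    factorsRow <- vapply(nonAnchor, function(s) {
      v <- factors[[s]]
      if (is.null(v)) "" else as.character(v)[1]
    }, character(1), USE.NAMES = FALSE)
  }
  MWTabTable(role = role, units = units, columns = columns,
             factorsRow = factorsRow, rows = rows)
}

jsonToSSF <- function(recList) {
  records <- lapply(recList, function(r) {
    fct <- r[["Factors"]]
    add <- r[["Additional sample data"]]
    toMap <- function(obj) {
      dm <- DuplicatesMap()
      for (i in seq_along(obj))
        dm <- mapAppend(dm, names(obj)[i], jsonScalarToText(obj[[i]]))
      dm
    }
    SSFRecord(
      subjectId = if (is.null(r[["Subject ID"]])) "" else as.character(r[["Subject ID"]]),
      sampleId = if (is.null(r[["Sample ID"]])) "" else as.character(r[["Sample ID"]]),
      factors = if (is.list(fct)) toMap(fct) else DuplicatesMap(),
      additionalData = if (is.list(add)) toMap(add) else DuplicatesMap())
  })
  SubjectSampleFactors(records = records)
}

#' Parse JSON analysis text into a document
#'
#' Duplicate keys below the top level are preserved in order (the
#' duplicate-member JSON dialect produced by the repository's converters);
#' duplicate keys at the top level are refused -- they cannot be attributed
#' to sections. Header attributes are accepted either nested under a
#' `"METABOLOMICS WORKBENCH"` member or as top-level scalars.
#'
#' @param text JSON text.
#' @param force Skip (with a warning) non-object values found in table row
#'   lists instead of refusing the file. Default `FALSE`.
#' @return A [MWTabDocument-class] with `sourceFormat = "json"`.
#' @export
parseMWTabJSON <- function(text, force = FALSE) {
  parsed <- tryCatch(
    jsonlite::fromJSON(text, simplifyVector = FALSE),
    error = function(e)
      parseError(paste("malformed JSON:", conditionMessage(e)),
                 class = "mwtab_parse_error_json_malformed"))
  if (!is.list(parsed) || is.null(names(parsed)))
    parseError("top level of JSON must be an object",
               class = "mwtab_parse_error_json_malformed")
  topNames <- names(parsed)
  dupTop <- unique(topNames[duplicated(topNames)])
  if (length(dupTop))
    parseError(paste("duplicate keys at the top level of the JSON:",
                     paste(dupTop, collapse = ", ")),
               class = "mwtab_parse_error_json_top_level_duplicate")

  sections <- DuplicatesMap()
  headerItems <- DuplicatesMap()
  pendingHeaderFirst <- TRUE
  for (i in seq_along(parsed)) {
    name <- topNames[i]
    v <- parsed[[i]]
    if (name == HEADER_SECTION) {
      blk <- jsonObjectToBlock(v)
      for (j in seq_along(blk@items@keys))
        headerItems <- mapAppend(headerItems, blk@items@keys[j], blk@items@values[[j]])
    } else if (name == "SUBJECT_SAMPLE_FACTORS") {
      if (!is.list(v)) parseError("SUBJECT_SAMPLE_FACTORS must be an array",
                                  class = "mwtab_parse_error_json_malformed")
      sections <- mapAppend(sections, name, jsonToSSF(v))
    } else if (name %in% TABLE_COMPOSITE_SECTIONS && is.list(v) &&
               !is.null(names(v))) {
      units <- if (!is.null(v[["Units"]])) as.character(v[["Units"]]) else character(0)
      role <- tableRoleForSection(name)
      dataRows <- if (is.null(v[["Data"]])) list() else v[["Data"]]
      sections <- mapAppend(sections, name,
        jsonRowsToTable(dataRows, role, name, force, units = units,
                        factors = v[["Factors"]]))
      if (!is.null(v[["Metabolites"]]))
        sections <- mapAppend(sections, "METABOLITES",
          jsonRowsToTable(v[["Metabolites"]], "METABOLITES", "METABOLITES", force))
      if (!is.null(v[["Extended"]])) {
        extName <- if (name == "NMR_METABOLITE_DATA")
          "EXTENDED_NMR_METABOLITE_DATA" else "EXTENDED_MS_METABOLITE_DATA"
        sections <- mapAppend(sections, extName,
          jsonRowsToTable(v[["Extended"]], "EXTENDED", extName, force))
      }
    } else if (is.list(v) && !is.null(names(v))) {
      sections <- mapAppend(sections, name, jsonObjectToBlock(v))
    } else if (is.list(v)) {
      # unnamed list in an unexpected place: keep as an empty block
      sections <- mapAppend(sections, name, KeyValueBlock())
    } else {
      # top-level scalar: flat-header variant
      headerItems <- mapAppend(headerItems, name, jsonScalarToText(v))
    }
  }
  if (length(headerItems@keys)) {
    full <- DuplicatesMap()
    full <- mapAppend(full, HEADER_SECTION, KeyValueBlock(items = headerItems))
    for (j in seq_along(sections@keys))
      full <- mapAppend(full, sections@keys[j], sections@values[[j]])
    sections <- full
  }
  MWTabDocument(sections = sections, sourceFormat = "json",
                annotations = emptyAnnotations())
}

#' Read a JSON analysis file
#'
#' @param path Path to a UTF-8 JSON file.
#' @inheritParams parseMWTabJSON
#' @return A [MWTabDocument-class].
#' @export
readMWTabJSON <- function(path, force = FALSE) {
  text <- readFileUTF8(path)
  withCallingHandlers(
    parseMWTabJSON(text, force = force),
    error = function(e) {
      if (inherits(e, "mwtab_parse_error") && is.null(attr(e, "mwtab_file"))) {
        e$message <- sprintf("%s: %s", path, conditionMessage(e))
        attr(e, "mwtab_file") <- path
        stop(e)
      }
    })
}

# ---- writing ---------------------------------------------------------------

jsonEscape <- function(x) {
  x <- gsub("\\", "\\\\", x, fixed = TRUE)
  x <- gsub("\"", "\\\"", x, fixed = TRUE)
  x <- gsub("\n", "\\n", x, fixed = TRUE)
  x <- gsub("\r", "\\r", x, fixed = TRUE)
  x <- gsub("\t", "\\t", x, fixed = TRUE)
  x
}

jsonString <- function(x) paste0("\"", jsonEscape(enc2utf8(as.character(x))), "\"")

jsonScalar <- function(v) {
  if (is.null(v) || (length(v) == 1 && is.na(v))) "null" else jsonString(v)
}

# Emit an object from parallel keys/values, duplicate members allowed.
jsonObject <- function(keys, values, indent) {
  if (length(keys) == 0) return("{}")
  pad <- strrep(" ", indent + 2)
  body <- vapply(seq_along(keys), function(i) {
    v <- values[[i]]
    vtxt <- if (is.list(v))
      paste0("[", paste(vapply(v, jsonScalar, character(1)), collapse = ", "), "]")
    else jsonScalar(v)
    paste0(pad, jsonString(keys[i]), ": ", vtxt)
  }, character(1))
  paste0("{\n", paste(body, collapse = ",\n"), "\n", strrep(" ", indent), "}")
}

jsonTableRows <- function(rows, indent) {
  if (length(rows) == 0) return("[]")
  pad <- strrep(" ", indent + 2)
  body <- vapply(rows, function(r)
    paste0(pad, jsonObject(r@keys, r@values, indent + 2)), character(1))
  paste0("[\n", paste(body, collapse = ",\n"), "\n", strrep(" ", indent), "]")
}

jsonSSF <- function(ssf, indent) {
  if (length(ssf@records) == 0) return("[]")
  pad <- strrep(" ", indent + 2)
  body <- vapply(ssf@records, function(rec) {
    keys <- c("Subject ID", "Sample ID", "Factors", "Additional sample data")
    inner <- c(
      paste0(jsonString(keys[1]), ": ", jsonScalar(rec@subjectId)),
      paste0(jsonString(keys[2]), ": ", jsonScalar(rec@sampleId)),
      paste0(jsonString(keys[3]), ": ",
             jsonObject(rec@factors@keys, rec@factors@values, indent + 4)),
      paste0(jsonString(keys[4]), ": ",
             jsonObject(rec@additionalData@keys, rec@additionalData@values,
                        indent + 4)))
    paste0(pad, "{\n", paste0(strrep(" ", indent + 4), inner, collapse = ",\n"),
           "\n", pad, "}")
  }, character(1))
  paste0("[\n", paste(body, collapse = ",\n"), "\n", strrep(" ", indent), "]")
}

#' Serialize a document to JSON text
#'
#' Duplicate keys are re-emitted as repeated object members in stored order
#' (standard JSON writers refuse this, hence the dedicated serializer). The
#' DATA composite nests its `Metabolites`/`Extended` tables and, when the
#' document carries one, the `Factors` preamble row, so that a JSON round
#' trip loses nothing. Output is byte-deterministic.
#'
#' @param doc A [MWTabDocument-class].
#' @return A single UTF-8 JSON string.
#' @export
formatMWTabJSON <- function(doc) {
  names <- orderedSectionNames(doc)
  parts <- character(0)
  emitted <- character(0)
  for (name in names) {
    if (name %in% c("METABOLITES", "EXTENDED_MS_METABOLITE_DATA",
                    "EXTENDED_NMR_METABOLITE_DATA"))
      next  # nested under their data composite
    idx <- which(doc@sections@keys == name)
    for (i in idx) {
      content <- doc@sections@values[[i]]
      if (is(content, "KeyValueBlock")) {
        val <- jsonObject(content@items@keys, content@items@values, 2)
      } else if (is(content, "SubjectSampleFactors")) {
        val <- jsonSSF(content, 2)
      } else if (is(content, "MWTabTable")) {
        inner <- character(0)
        if (length(content@units))
          inner <- c(inner, paste0(jsonString("Units"), ": ",
                                   jsonString(content@units[1])))
        if (length(content@factorsRow)) {
          nonAnchor <- content@columns[content@columns != CANONICAL_ANCHOR]
          inner <- c(inner, paste0(jsonString("Factors"), ": ",
                                   jsonObject(nonAnchor,
                                              as.list(content@factorsRow), 4)))
        }
        inner <- c(inner, paste0(jsonString("Data"), ": ",
                                 jsonTableRows(content@rows, 4)))
        met <- getSection(doc, "METABOLITES")
        if (!is.null(met) && is(met, "MWTabTable"))
          inner <- c(inner, paste0(jsonString("Metabolites"), ": ",
                                   jsonTableRows(met@rows, 4)))
        extName <- if (name == "NMR_METABOLITE_DATA")
          "EXTENDED_NMR_METABOLITE_DATA" else "EXTENDED_MS_METABOLITE_DATA"
        ext <- getSection(doc, extName)
        if (!is.null(ext) && is(ext, "MWTabTable") && name != "NMR_BINNED_DATA")
          inner <- c(inner, paste0(jsonString("Extended"), ": ",
                                   jsonTableRows(ext@rows, 4)))
        val <- paste0("{\n", paste0("    ", inner, collapse = ",\n"), "\n  }")
      } else next
      parts <- c(parts, paste0("  ", jsonString(name), ": ", val))
    }
  }
  paste0("{\n", paste(parts, collapse = ",\n"), "\n}\n")
}

#' Write a document as a JSON file
#'
#' Missing output directories are created rather than treated as fatal.
#'
#' @param doc A [MWTabDocument-class].
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
writeMWTabJSON <- function(doc, path) {
  writeFileUTF8(formatMWTabJSON(doc), path)
}
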