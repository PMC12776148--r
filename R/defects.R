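#' @include fixtures.R
NULL

PARSE_DEFECT_CLASSES <- c(
  "ssf_missing_semicolon", "ssf_extra_equals", "ssf_extra_colon",
  "missing_tab", "embedded_carriage_return", "multiple_data_end",
  "json_malformed", "json_false_row", "json_top_level_duplicate")

#' Applicability matrix of injectable validation defects
#'
#' One row per (check ID, format) pair for which [injectDefect()] can
#' synthesize a still-parsable defective file; mirrors the check registry's
#' applicability column.
#'
#' @return Data frame with columns `id` and `format`.
#' @export
defectApplicability <- function() {
  reg <- getCheckRegistry()
  do.call(rbind, lapply(seq_len(nrow(reg)), function(i) {
    fmts <- switch(reg$applicability[i], mwtab = "mwtab", json = "json",
                   both = c("mwtab", "json"))
    data.frame(id = reg$id[i], format = fmts, stringsAsFactors = FALSE)
  }))
}

# ---- model mutation helpers ------------------------------------------------

replaceSection <- function(doc, name, content) {
  i <- which(doc@sections@keys == name)[1]
  doc@sections@values[[i]] <- content
  doc
}

dropSection <- function(doc, name) {
  doc@sections <- mapDrop(doc@sections, name)
  doc
}

firstTableName <- function(doc, roles) findTable(doc, roles)$name

mutateTable <- function(doc, roles, fun) {
  hit <- findTable(doc, roles)
  replaceSection(doc, hit$name, fun(hit$table))
}

setRowCell <- function(tab, row, column, value) {
  r <- tab@rows[[row]]
  i <- which(r@keys == column)[1]
  r@values[[i]] <- value
  tab@rows[[row]] <- r
  tab
}

addTableColumn <- function(tab, name, values, after = length(tab@columns)) {
  pos <- after
  tab@columns <- append(tab@columns, name, after = pos)
  for (i in seq_along(tab@rows)) {
    r <- tab@rows[[i]]
    r@keys <- append(r@keys, name, after = pos)
    r@values <- append(r@values, list(values[i]), after = pos)
    tab@rows[[i]] <- r
  }
  tab
}

dropTableColumn <- function(tab, name) {
  keep <- tab@columns != name
  tab@columns <- tab@columns[keep]
  for (i in seq_along(tab@rows)) tab@rows[[i]] <- mapDrop(tab@rows[[i]], name)
  tab
}

renameTableColumn <- function(tab, old, new) {
  tab@columns[tab@columns == old] <- new
  for (i in seq_along(tab@rows)) {
    r <- tab@rows[[i]]
    r@keys[r@keys == old] <- new
    tab@rows[[i]] <- r
  }
  tab
}

addTableRow <- function(tab, values) {
  tab@rows[[length(tab@rows) + 1]] <- DuplicatesMap(tab@columns, as.list(values))
  tab
}

mutateBlock <- function(doc, name, fun) {
  blk <- getSection(doc, name)
  blk@items <- fun(blk@items)
  replaceSection(doc, name, blk)
}

mutateSSF <- function(doc, fun) {
  ssf <- getSection(doc, "SUBJECT_SAMPLE_FACTORS")
  replaceSection(doc, "SUBJECT_SAMPLE_FACTORS", fun(ssf))
}

# ---- text surgery helpers --------------------------------------------------

mwtabLines <- function(text) strsplit(text, "\n", fixed = TRUE)[[1]]
joinLines <- function(lines) paste0(paste(lines, collapse = "\n"), "\n")

dataStartIndex <- function(lines) {
  grep("^(MS|NMR)_(METABOLITE|BINNED)_DATA_START$", lines)[1]
}

editLine <- function(lines, idx, fun) { lines[idx] <- fun(lines[idx]); lines }

editCells <- function(lines, idx, fun) {
  editLine(lines, idx, function(l) {
    cells <- strsplit(l, "\t", fixed = TRUE)[[1]]
    paste(fun(cells), collapse = "\t")
  })
}

#' Inject a validation defect into a synthetic fixture
#'
#' Produces a serialized analysis file that still parses but whose
#' validation output contains `validationId`. Defects bound to the flat
#' text's physical layout (duplicate subsections, bad headers, factor
#' mismatches, duplicate sample columns, duplicate column names) are
#' injected by text surgery; everything else is a model-level mutation
#' serialized to the target format. Injection may imply further findings
#' (e.g. a duplicated data metabolite also breaks the DATA/METABOLITES
#' correspondence); the target ID is always present.
#'
#' @param validationId Check ID 1--36.
#' @param format Target serialization, `"mwtab"` or `"json"`; the pair must
#'   appear in [defectApplicability()].
#' @param seed,nSamples,nMetabolites,mode Passed to [generateFixture()];
#'   EXTENDED-table checks force `includeExtended`.
#' @return List with `text` (the defective file), `format` and `id`.
#' @export
injectDefect <- function(validationId, format = c("mwtab", "json"), seed = 1,
                         nSamples = 4, nMetabolites = 12, mode = "MS") {
  format <- match.arg(format)
  app <- defectApplicability()
  if (!any(app$id == validationId & app$format == format))
    stop("validation ", validationId, " is not applicable to ", format,
         " formatted files")
  needExt <- validationId %in% c(21, 22, 35, 36)
  fix <- generateFixture(seed = seed, nSamples = max(nSamples, 2),
                         nMetabolites = max(nMetabolites, 10), mode = mode,
                         includeExtended = needExt)
  doc <- fix$document
  ssfRecs <- getSection(doc, "SUBJECT_SAMPLE_FACTORS")@records
  s1 <- ssfRecs[[1]]@sampleId

  textSurgery <- function() {
    lines <- mwtabLines(fix$mwtab)
    ds <- dataStartIndex(lines)
    metHeader <- grep("^METABOLITES_START$", lines)[1] + 1
    switch(as.character(validationId),
      "1" = { i <- grep("^CO:COLLECTION_SUMMARY\t", lines)[1]
              lines <- append(lines, lines[i], after = i) },
      "2" = lines <- editLine(lines, ds + 3,
                              function(l) paste0(l, "\tSTRAY\tCELLS")),
      "3" = lines <- editCells(lines, ds + 2,
                               function(cells) { cells[2] <- "Treatment:Mutant"; cells }),
      "8" = lines <- editCells(lines, ds + 1,
                               function(cells) { cells[3] <- cells[2]; cells }),
      "30" = lines <- editCells(lines, metHeader,
                                function(cells) { cells[3] <- cells[2]; cells }),
      "34" = lines <- editCells(lines, metHeader,
                                function(cells) { cells[1] <- "metabolite_name"; cells }),
      stop("no text-level recipe for validation ", validationId))
    joinLines(lines)
  }

  modelMutation <- function() {
    switch(as.character(validationId),
      "4" = mutateSSF(doc, function(ssf) {
        ssf@records[[2]]@sampleId <- ssf@records[[1]]@sampleId; ssf }),
      "5" = mutateSSF(doc, function(ssf) {
        ssf@records[[1]]@factors <-
          mapAppend(ssf@records[[1]]@factors, "Treatment", "Case"); ssf }),
      "6" = mutateSSF(doc, function(ssf) {
        ssf@records[[1]]@additionalData <-
          mapAppend(ssf@records[[1]]@additionalData, "RAW_FILE_NAME", "dup.raw")
        ssf }),
      "7" = mutateSSF(doc, function(ssf) {
        ssf@records <- ssf@records[-length(ssf@records)]; ssf }),
      "9" = mutateTable(doc, "DATA", function(t)
        addTableRow(t, c("unobtainium", sprintf("%d.0", seq_len(length(t@columns) - 1))))),
      "10" = mutateTable(doc, "DATA", function(t)
        setRowCell(t, 1, CANONICAL_ANCHOR, "")),
      "11" = mutateTable(doc, "DATA", function(t)
        setRowCell(t, 2, CANONICAL_ANCHOR, cellText(mapGet(t@rows[[1]], CANONICAL_ANCHOR)[[1]]))),
      "12" = mutateTable(doc, "METABOLITES", function(t)
        addTableRow(t, c("unobtainium", "100.0000", "1.00", "100000",
                         "Fiehn RI", "C99999"))),
      "13" = mutateTable(doc, "METABOLITES", function(t)
        setRowCell(t, 1, CANONICAL_ANCHOR, "")),
      "14" = mutateTable(doc, "METABOLITES", function(t)
        setRowCell(t, 2, CANONICAL_ANCHOR, cellText(mapGet(t@rows[[1]], CANONICAL_ANCHOR)[[1]]))),
      "15" = mutateTable(doc, "METABOLITES", function(t)
        renameTableColumn(t, "moverz_quant", "m/z")),
      "16" = mutateTable(doc, "METABOLITES", function(t)
        setRowCell(t, 1, "kegg_id", "banana")),
      "17" = mutateTable(doc, "METABOLITES", function(t)
        dropTableColumn(t, "retention_index_type")),
      "18" = mutateTable(doc, "METABOLITES", function(t)
        setRowCell(t, 1, "retention_index_type", "")),
      "19" = mutateTable(doc, "METABOLITES", function(t) {
        t <- addTableColumn(t, "other_id", sprintf("X%03d", seq_along(t@rows)))
        addTableColumn(t, "other_id_type", rep("LocalDB", length(t@rows))) }),
      "20" = mutateTable(doc, "METABOLITES", function(t)
        renameTableColumn(t, "retention_time", "retention")),
      "21" = mutateTable(doc, "EXTENDED", function(t)
        renameTableColumn(t, "sample_id", "specimen")),
      "22" = mutateTable(doc, "EXTENDED", function(t) {
        last <- ssfRecs[[length(ssfRecs)]]@sampleId
        keep <- vapply(t@rows, function(r)
          !identical(cellText(mapGet(r, "sample_id")[[1]]), last), logical(1))
        t@rows <- t@rows[keep]; t }),
      "23" = mutateTable(doc, "DATA", function(t)
        setRowCell(t, 1, CANONICAL_ANCHOR, "metabolite_name")),
      "24" = mutateBlock(doc, "SUBJECT", function(items)
        mapDrop(items, "SUBJECT_TYPE")),
      "25" = mutateTable(doc, "DATA", function(t) {
        t@rows[[2]] <- mapDrop(t@rows[[2]], s1); t }),
      "26" = mutateTable(doc, "METABOLITES", function(t)
        addTableColumn(t, "", sprintf("x%d", seq_along(t@rows)), after = 1)),
      "27" = mutateTable(doc, "METABOLITES", function(t)
        addTableColumn(t, "curation_note", rep("", length(t@rows)))),
      "28" = mutateTable(doc, "METABOLITES", function(t)
        addTableColumn(t, "batch", c(rep("B1", length(t@rows) - 1), "B2"))),
      "29" = mutateTable(doc, "METABOLITES", function(t) {
        t@rows[[length(t@rows) + 1]] <- t@rows[[1]]; t }),
      "31" = mutateTable(doc, "METABOLITES", function(t)
        addTableColumn(t, "polarity",
                       rep(c("POS", "NEG"), length.out = length(t@rows)))),
      "32" = dropSection(dropSection(doc, "MS"), "NM"),
      "33" = dropSection(doc, "METABOLITES"),
      "34" = mutateTable(doc, "METABOLITES", function(t)
        renameTableColumn(t, CANONICAL_ANCHOR, "metabolite_name")),
      "35" = mutateTable(doc, "EXTENDED", function(t)
        setRowCell(t, 1, "sample_id", "")),
      "36" = mutateTable(doc, "EXTENDED", function(t)
        setRowCell(t, 1, CANONICAL_ANCHOR, "")),
      stop("no model-level recipe for validation ", validationId))
  }

  textLevel <- c(1, 2, 3, 8, 30)
  text <- if (validationId %in% textLevel ||
              (validationId == 34 && format == "mwtab")) {
    stopifnot(format == "mwtab")
    textSurgery()
  } else {
    mutated <- modelMutation()
    formatDocument(mutated, format)
  }
  list(text = text, format = format, id = validationId)
}

#' Inject an unparsable defect into a synthetic fixture
#'
#' Synthesizes a file of one of the nine refusal classes observed in real
#' depositions; reading the result raises the matching classed parse error
#' (`json_false_row` parses when forced).
#'
#' @param defectClass One of `ssf_missing_semicolon`, `ssf_extra_equals`,
#'   `ssf_extra_colon`, `missing_tab`, `embedded_carriage_return`,
#'   `multiple_data_end`, `json_malformed`, `json_false_row`,
#'   `json_top_level_duplicate`.
#' @param seed,nSamples,nMetabolites Passed to [generateFixture()].
#' @return List with `text`, `format` (`"mwtab"` or `"json"`) and
#'   `errorClass` (the condition class the reader raises).
#' @export
injectParseDefect <- function(defectClass, seed = 1, nSamples = 4,
                              nMetabolites = 6) {
  if (!defectClass %in% PARSE_DEFECT_CLASSES)
    stop("unknown parse defect class: ", defectClass)
  fix <- generateFixture(seed = seed, nSamples = nSamples,
                         nMetabolites = nMetabolites)
  lines <- mwtabLines(fix$mwtab)
  ssfIdx <- grep("^SUBJECT_SAMPLE_FACTORS\t", lines)[1]
  ds <- dataStartIndex(lines)
  json <- fix$json
  out <- function(text, format, errorClass)
    list(text = text, format = format,
         errorClass = paste0("mwtab_parse_error_", errorClass))
  switch(defectClass,
    ssf_missing_semicolon = out(joinLines(editCells(lines, ssfIdx,
      function(cells) { cells[5] <- "RAW_FILE_NAME=run.raw BATCH=1"; cells })),
      "mwtab", "ssf"),
    ssf_extra_equals = out(joinLines(editCells(lines, ssfIdx,
      function(cells) { cells[5] <- "RAW_FILE_NAME=run=001.raw"; cells })),
      "mwtab", "ssf"),
    ssf_extra_colon = out(joinLines(editCells(lines, ssfIdx,
      function(cells) { cells[4] <- "Dose:5:mg"; cells })),
      "mwtab", "ssf"),
    missing_tab = out(joinLines(editLine(lines,
      grep("^CO:COLLECTION_SUMMARY\t", lines)[1],
      function(l) sub("\t", " ", l, fixed = TRUE))),
      "mwtab", "missing_tab"),
    embedded_carriage_return = out(joinLines(editLine(lines,
      grep("^TR:TREATMENT_SUMMARY\t", lines)[1],
      function(l) sub("treatment arm", "treatment\narm carried to a new line",
                      l, fixed = TRUE))),
      "mwtab", "orphan_line"),
    multiple_data_end = out(joinLines(append(lines,
      sub("_START$", "_END", lines[ds]), after = ds + 3)),
      "mwtab", "multiple_data_end"),
    json_malformed = out(substr(json, 1, nchar(json) - 3), "json",
                         "json_malformed"),
    json_false_row = out(sub('(?s)("Data": \\[\n).*?\n {6}\\},',
                             "\\1      false,", json, perl = TRUE),
                         "json", "json_false_row"),
    json_top_level_duplicate = out(sub("\n\\}\n$",
      ",\n  \"PROJECT\": {\n    \"PROJECT_TITLE\": \"duplicate\"\n  }\n}\n",
      json), "json", "json_top_level_duplicate"))
}
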