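#' @include AllGenerics.R
NULL

#' Ordered key/value container that retains duplicate keys
#'
#' The backbone of lossless parsing. Insertion order is preserved exactly and
#' repeated keys are all retained; a map with no repeated keys behaves like a
#' plain ordered mapping. Values may be any R object (section values are text;
#' JSON subsections may carry lists).
#'
#' @slot keys Character vector of keys in insertion order.
#' @slot values Unnamed list of values, parallel to `keys`.
#'
#' @seealso [mapGet()], [mapGetOne()], [mapAppend()], [mapSet()]
#' @export
setClass("DuplicatesMap",
         representation(keys = "character", values = "list"),
         prototype(keys = character(0), values = list()))

setValidity("DuplicatesMap", function(object) {
  if (length(object@keys) != length(object@values))
    return("keys and values must have equal length")
  if (anyNA(object@keys))
    return("keys must not be NA")
  TRUE
})

#' Construct a DuplicatesMap
#'
#' @param keys Character vector of keys (duplicates allowed), or a named list
#'   when `values` is missing.
#' @param values List (or vector) of values parallel to `keys`.
#' @return A [DuplicatesMap-class] object.
#' @examples
#' m <- DuplicatesMap(c("a", "a"), list("1", "2"))
#' mapGet(m, "a")
#' @export
DuplicatesMap <- function(keys = character(0), values) {
  if (missing(values)) {
    if (is.list(keys)) {
      values <- unname(keys)
      keys <- if (length(keys)) names(keys) else character(0)
      if (is.null(keys)) stop("a list given alone must be named")
    } else if (length(keys) == 0) {
      values <- list()
    } else stop("values missing")
  }
  if (!is.list(values)) values <- as.list(values)
  new("DuplicatesMap", keys = as.character(keys), values = unname(values))
}

#' Key/value subsection block of one mwTab section
#'
#' @slot items A [DuplicatesMap-class] of subsection name to value. An empty
#'   string value and an absent key are distinct, representable states (real
#'   depositions mix both conventions).
#' @export
setClass("KeyValueBlock", representation(items = "DuplicatesMap"))

#' @rdname KeyValueBlock-class
#' @param items A [DuplicatesMap-class].
#' @export
KeyValueBlock <- function(items = DuplicatesMap()) new("KeyValueBlock", items = items)

#' One SUBJECT_SAMPLE_FACTORS record
#'
#' @slot subjectId Subject identifier (may be blank; optional per format).
#' @slot sampleId Sample identifier.
#' @slot factors [DuplicatesMap-class] of experimental factors
#'   (serialized as `key:value` pairs joined by `|`).
#' @slot additionalData [DuplicatesMap-class] of additional sample data
#'   (serialized as `key=value` pairs joined by `;`).
#' @slot rawLine The raw source line (mwTab sources only; length 0 otherwise).
#' @export
setClass("SSFRecord",
         representation(subjectId = "character", sampleId = "character",
                        factors = "DuplicatesMap", additionalData = "DuplicatesMap",
                        rawLine = "character"),
         prototype(subjectId = "", sampleId = "", rawLine = character(0)))

#' @rdname SSFRecord-class
#' @param subjectId,sampleId,factors,additionalData,rawLine See slots.
#' @export
SSFRecord <- function(subjectId = "", sampleId = "",
                      factors = DuplicatesMap(), additionalData = DuplicatesMap(),
                      rawLine = character(0)) {
  new("SSFRecord", subjectId = subjectId, sampleId = sampleId,
      factors = factors, additionalData = additionalData, rawLine = rawLine)
}

#' The SUBJECT_SAMPLE_FACTORS section
#'
#' @slot records List of [SSFRecord-class] objects in file order.
#' @export
setClass("SubjectSampleFactors", representation(records = "list"))

setValidity("SubjectSampleFactors", function(object) {
  if (!all(vapply(object@records, is, logical(1), "SSFRecord")))
    return("all records must be SSFRecord objects")
  TRUE
})

#' @rdname SubjectSampleFactors-class
#' @param records List of [SSFRecord-class] objects.
#' @export
SubjectSampleFactors <- function(records = list()) new("SubjectSampleFactors", records = records)

#' One tabular section (DATA, METABOLITES, EXTENDED or NMR_BINNED)
#'
#' Cells are stored as text; numeric interpretation happens only in
#' validators (lossless round-tripping trumps typed convenience). For tables
#' built from mwTab text every row carries exactly the header's columns after
#' harmonization and the anchor column is canonically named `"Metabolite"`;
#' JSON-origin rows are kept as read (their column sets may disagree, which
#' the validator detects).
#'
#' @slot role One of `"DATA"`, `"METABOLITES"`, `"EXTENDED"`, `"NMR_BINNED"`.
#' @slot units Units line of a DATA table (length 0 when absent).
#' @slot columns Ordered column names, duplicates allowed. For DATA tables
#'   the non-anchor columns are the sample IDs.
#' @slot factorsRow Factor strings of the `Factors` preamble row, parallel to
#'   the non-anchor columns (mwTab sources only; length 0 otherwise).
#' @slot rows List of [DuplicatesMap-class], one per data row
#'   (column name -> cell text).
#' @export
setClass("MWTabTable",
         representation(role = "character", units = "character",
                        columns = "character", factorsRow = "character",
                        rows = "list"),
         prototype(role = "DATA", units = character(0),
                   columns = character(0), factorsRow = character(0),
                   rows = list()))

setValidity("MWTabTable", function(object) {
  if (!object@role %in% c("DATA", "METABOLITES", "EXTENDED", "NMR_BINNED"))
    return("unknown table role")
  if (!all(vapply(object@rows, is, logical(1), "DuplicatesMap")))
    return("rows must be DuplicatesMap objects")
  TRUE
})

#' @rdname MWTabTable-class
#' @param role,units,columns,factorsRow,rows See slots.
#' @export
MWTabTable <- function(role = "DATA", units = character(0), columns = character(0),
                       factorsRow = character(0), rows = list()) {
  new("MWTabTable", role = role, units = units, columns = columns,
      factorsRow = factorsRow, rows = rows)
}

emptyAnnotations <- function() {
  list(
    duplicateSubsections = data.frame(section = character(0), subsection = character(0),
                                      stringsAsFactors = FALSE),
    headerMismatches = data.frame(section = character(0), row = integer(0),
                                  observed = integer(0), expected = integer(0),
                                  stringsAsFactors = FALSE),
    bogusSectionLines = integer(0),
    duplicateSampleColumns = data.frame(section = character(0), column = character(0),
                                        stringsAsFactors = FALSE),
    duplicateColumnNames = data.frame(section = character(0), column = character(0),
                                      stringsAsFactors = FALSE),
    anchorMismatches = data.frame(section = character(0), observed = character(0),
                                  stringsAsFactors = FALSE)
  )
}

annotationsEmpty <- function(ann) {
  all(vapply(ann, function(x) NROW(x) == 0, logical(1)))
}

#' In-memory representation of one Metabolomics Workbench analysis file
#'
#' An ordered, typed model of one analysis, independent of whether it came
#' from mwTab flat text or JSON. The METABOLOMICS WORKBENCH header block is
#' the first section; [headerFields()] gives direct access to its attributes.
#' Section names outside the mwTab vocabulary (the notorious `#FACTORS` case)
#' are retained and flagged in the parse annotations, never dropped.
#'
#' @slot sections [DuplicatesMap-class] of section name to content
#'   ([KeyValueBlock-class], [SubjectSampleFactors-class] or
#'   [MWTabTable-class]).
#' @slot sourceFormat `"mwtab"` or `"json"`.
#' @slot annotations List of parse-time facts; see [parseAnnotations()].
#' @export
setClass("MWTabDocument",
         representation(sections = "DuplicatesMap", sourceFormat = "character",
                        annotations = "list"),
         prototype(sourceFormat = "mwtab"))

setValidity("MWTabDocument", function(object) {
  if (!object@sourceFormat %in% c("mwtab", "json"))
    return("sourceFormat must be 'mwtab' or 'json'")
  ok <- vapply(object@sections@values, function(s)
    is(s, "KeyValueBlock") || is(s, "SubjectSampleFactors") || is(s, "MWTabTable"),
    logical(1))
  if (!all(ok)) return("sections must be KeyValueBlock, SubjectSampleFactors or MWTabTable")
  TRUE
})

#' @rdname MWTabDocument-class
#' @param sections,sourceFormat,annotations See slots.
#' @export
MWTabDocument <- function(sections = DuplicatesMap(), sourceFormat = "mwtab",
                          annotations = emptyAnnotations()) {
  new("MWTabDocument", sections = sections, sourceFormat = sourceFormat,
      annotations = annotations)
}

#' A single column finder: canonical name, matching rules, value rule
#'
#' @slot canonical The canonical standard column name.
#' @slot patterns Character vector of full-match regular expressions applied
#'   to the normalized column name (see [normalizeColumnName()]).
#' @slot valuePattern Optional full-match regular expression a non-empty cell
#'   of this column must satisfy (length 0 when the column has no value rule).
#' @slot impliedPartners Canonical names of columns this column implies
#'   (e.g. `retention_index` implies `retention_index_type`).
#' @slot exclusiveWith Canonical names this finder may deliberately overlap
#'   with (exempt from the registry self-consistency rule).
#' @export
setClass("ColumnFinder",
         representation(canonical = "character", patterns = "character",
                        valuePattern = "character", impliedPartners = "character",
                        exclusiveWith = "character"),
         prototype(valuePattern = character(0), impliedPartners = character(0),
                   exclusiveWith = character(0)))

#' @rdname ColumnFinder-class
#' @param canonical,patterns,valuePattern,impliedPartners,exclusiveWith See slots.
#' @export
ColumnFinder <- function(canonical, patterns, valuePattern = character(0),
                         impliedPartners = character(0), exclusiveWith = character(0)) {
  new("ColumnFinder", canonical = canonical, patterns = patterns,
      valuePattern = valuePattern, impliedPartners = impliedPartners,
      exclusiveWith = exclusiveWith)
}
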