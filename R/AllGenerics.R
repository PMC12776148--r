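#' @include AllGenerics.R
NULL

#' Keys of a duplicate-preserving map
#'
#' @param x A [DuplicatesMap-class] object.
#' @return Character vector of keys in insertion order (possibly repeated).
#' @export
setGeneric("mapKeys", function(x) standardGeneric("mapKeys"))

#' Values of a duplicate-preserving map
#'
#' @param x A [DuplicatesMap-class] object.
#' @return Unnamed list of values in insertion order.
#' @export
setGeneric("mapValues", function(x) standardGeneric("mapValues"))

#' Retrieve all values stored under a key
#'
#' Returns the ordered list of every value stored under `key`; duplicate
#' keys contribute one element each, in insertion order.
#'
#' @param x A [DuplicatesMap-class] object.
#' @param key Single key to look up.
#' @return List of values (empty list when the key is absent).
#' @export
setGeneric("mapGet", function(x, key) standardGeneric("mapGet"))

#' Retrieve the single value stored under a key
#'
#' Convenience accessor that errors when the key is duplicated, forcing the
#' caller to confront duplication instead of silently taking one value.
#'
#' @inheritParams mapGet
#' @param default Value returned when the key is absent.
#' @return The single stored value, or `default`.
#' @export
setGeneric("mapGetOne", function(x, key, default = NULL) standardGeneric("mapGetOne"))

#' Append a key/value pair
#'
#' Always appends, even when the key is already present.
#'
#' @inheritParams mapGet
#' @param value Value to store.
#' @return The modified map.
#' @export
setGeneric("mapAppend", function(x, key, value) standardGeneric("mapAppend"))

#' Set the value for a key
#'
#' Replaces every existing occurrence of `key` with a single entry holding
#' `value` (at the position of its first occurrence), or appends when absent.
#'
#' @inheritParams mapAppend
#' @return The modified map.
#' @export
setGeneric("mapSet", function(x, key, value) standardGeneric("mapSet"))

#' Test for the presence of a key
#'
#' @inheritParams mapGet
#' @return `TRUE` iff `key` occurs at least once.
#' @export
setGeneric("mapHas", function(x, key) standardGeneric("mapHas"))

#' Drop every occurrence of a key
#'
#' @inheritParams mapGet
#' @return The modified map.
#' @export
setGeneric("mapDrop", function(x, key) standardGeneric("mapDrop"))

#' Header attributes of a document
#'
#' Returns the attributes of the METABOLOMICS WORKBENCH header block
#' (VERSION, CREATED_ON, STUDY_ID, ANALYSIS_ID, PROJECT_ID and any others
#' present). Absent attributes are omitted, not `NA`-filled; a blank
#' attribute is present with value `""` -- the two states are distinct.
#'
#' @param doc A [MWTabDocument-class].
#' @return Named character vector in stored order.
#' @export
setGeneric("headerFields", function(doc) standardGeneric("headerFields"))

#' Ordered section names of a document
#'
#' @param doc A [MWTabDocument-class].
#' @return Character vector of section names in stored order.
#' @export
setGeneric("sectionNames", function(doc) standardGeneric("sectionNames"))

#' Retrieve one section of a document
#'
#' @param doc A [MWTabDocument-class].
#' @param name Section name, e.g. `"SUBJECT"` or `"MS_METABOLITE_DATA"`.
#' @return The section content object, or `NULL` when absent.
#' @export
setGeneric("getSection", function(doc, name) standardGeneric("getSection"))

#' Source format of a document
#'
#' @param doc A [MWTabDocument-class].
#' @return `"mwtab"` or `"json"`.
#' @export
setGeneric("sourceFormat", function(doc) standardGeneric("sourceFormat"))

#' Parse annotations of a document
#'
#' Facts recorded during parsing (duplicate subsections, header/row cell
#' count mismatches, bogus `#FACTORS` lines, duplicate sample columns,
#' duplicate column names, non-canonical anchor headers). Empty for a clean
#' file; never inferred after parsing.
#'
#' @param doc A [MWTabDocument-class].
#' @return A list with one element per annotation kind.
#' @export
setGeneric("parseAnnotations", function(doc) standardGeneric("parseAnnotations"))
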