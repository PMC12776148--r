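#' @include AllClasses.R
NULL

HEADER_SECTION <- "METABOLOMICS WORKBENCH"

# Sections drawn from the mwTab specification vocabulary; anything else is
# retained but flagged (the `#FACTORS` case).
KNOWN_SECTIONS <- c(
  HEADER_SECTION, "PROJECT", "STUDY", "SUBJECT", "SUBJECT_SAMPLE_FACTORS",
  "COLLECTION", "TREATMENT", "SAMPLEPREP", "CHROMATOGRAPHY", "ANALYSIS",
  "MS", "NM", "MS_METABOLITE_DATA", "NMR_METABOLITE_DATA", "NMR_BINNED_DATA",
  "METABOLITES", "EXTENDED_MS_METABOLITE_DATA", "EXTENDED_NMR_METABOLITE_DATA")

# Item-line prefix used when writing each section's subsections back out.
# Unknown sections have no prefix, which reproduces the known unreadable
# output for items swallowed by a bogus section.
SECTION_PREFIX <- c(
  PROJECT = "PR", STUDY = "ST", SUBJECT = "SU", COLLECTION = "CO",
  TREATMENT = "TR", SAMPLEPREP = "SP", CHROMATOGRAPHY = "CH", ANALYSIS = "AN",
  MS = "MS", NM = "NM",
  MS_METABOLITE_DATA = "MS_METABOLITE_DATA",
  NMR_METABOLITE_DATA = "NMR_METABOLITE_DATA",
  NMR_BINNED_DATA = "NMR_BINNED_DATA")

# Predefined write-out order (mwTab specification presentation order); the
# EXTENDED and METABOLITES tables follow their data composite.
CANONICAL_SECTION_ORDER <- c(
  HEADER_SECTION, "PROJECT", "STUDY", "SUBJECT", "SUBJECT_SAMPLE_FACTORS",
  "COLLECTION", "TREATMENT", "SAMPLEPREP", "CHROMATOGRAPHY", "ANALYSIS",
  "MS", "NM", "MS_METABOLITE_DATA", "NMR_METABOLITE_DATA", "NMR_BINNED_DATA",
  "METABOLITES", "EXTENDED_MS_METABOLITE_DATA", "EXTENDED_NMR_METABOLITE_DATA")

#' @rdname headerFields
#' @export
setMethod("headerFields", "MWTabDocument", function(doc) {
  block <- getSection(doc, HEADER_SECTION)
  if (is.null(block)) return(stats::setNames(character(0), character(0)))
  items <- block@items
  vals <- vapply(items@values, function(v) {
    if (is.null(v) || length(v) == 0) "" else as.character(v)[1]
  }, character(1))
  stats::setNames(vals, items@keys)
})

#' @rdname sectionNames
#' @export
setMethod("sectionNames", "MWTabDocument", function(doc) doc@sections@keys)

#' @rdname getSection
#' @export
setMethod("getSection", "MWTabDocument", function(doc, name) {
  hits <- which(doc@sections@keys == name)
  if (length(hits) == 0) return(NULL)
  doc@sections@values[[hits[1]]]
})

#' @rdname sourceFormat
#' @export
setMethod("sourceFormat", "MWTabDocument", function(doc) doc@sourceFormat)

#' @rdname parseAnnotations
#' @export
setMethod("parseAnnotations", "MWTabDocument", function(doc) doc@annotations)

setMethod("show", "MWTabDocument", function(object) {
  hf <- headerFields(object)
  cat("MWTabDocument (", object@sourceFormat, " origin)\n", sep = "")
  for (k in c("STUDY_ID", "ANALYSIS_ID")) {
    if (k %in% names(hf)) cat("  ", k, ": ", hf[[k]], "\n", sep = "")
  }
  cat("  sections:", paste(sectionNames(object), collapse = ", "), "\n")
  if (!annotationsEmpty(object@annotations))
    cat("  parse annotations present (see parseAnnotations())\n")
})

# Internal helpers shared by validator / consistency ------------------------

# First table with one of the given roles, with its section name.
findTable <- function(doc, roles) {
  for (i in seq_along(doc@sections@keys)) {
    s <- doc@sections@values[[i]]
    if (is(s, "MWTabTable") && s@role %in% roles)
      return(list(name = doc@sections@keys[i], table = s))
  }
  NULL
}

ssfSection <- function(doc) {
  s <- getSection(doc, "SUBJECT_SAMPLE_FACTORS")
  if (is.null(s) || !is(s, "SubjectSampleFactors")) NULL else s
}

# Cell text of a row for a (first occurrence of a) column; NULL when absent.
rowCell <- function(row, column) {
  hits <- which(row@keys == column)
  if (length(hits) == 0) return(NULL)
  v <- row@values[[hits[1]]]
  if (is.null(v)) NA_character_ else as.character(v)[1]
}

# Per-row values of a column across a table; NA for null, NA for absent too
# unless absentAsNull = FALSE in which case absent rows are dropped.
columnValues <- function(table, column) {
  vapply(table@rows, function(r) {
    v <- rowCell(r, column)
    if (is.null(v)) NA_character_ else v
  }, character(1))
}

isBlank <- function(x) is.na(x) | x == ""
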