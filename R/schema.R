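#' @include converter.R
NULL

#' Accession identifier patterns
#'
#' Builds the full-match regular expression for a Metabolomics Workbench
#' accession: studies are `ST` + 6 digits, analyses `AN` + 6 digits,
#' projects `PR` + 6 digits.
#'
#' @param kind `"study"`, `"analysis"` or `"project"`.
#' @return A full-match regular expression string.
#' @examples
#' grepl(idPattern("analysis"), "AN002312")
#' @export
idPattern <- function(kind = c("study", "analysis", "project")) {
  kind <- match.arg(kind)
  prefix <- switch(kind, study = "ST", analysis = "AN", project = "PR")
  paste0("^", prefix, "[0-9]{6}$")
}

#' Default structural schema rules
#'
#' One record per rule: `section`, `subsection` (blank = the section itself
#' is required), `required`, and an optional full-match `pattern`
#' constraining the value space. The rule set is declarative so that drift
#' in the mwTab specification is absorbed by data edits, not code changes;
#' load a corrected table from file with [readSchemaRules()].
#'
#' The five CHROMATOGRAPHY attributes promoted from optional to required in
#' the 2023-08-01 specification update are required here
#' (CHROMATOGRAPHY_TYPE, INSTRUMENT_NAME, COLUMN_NAME, SOLVENT_A,
#' SOLVENT_B).
#'
#' @return Data frame of schema rules.
#' @export
defaultSchemaRules <- function() {
  r <- function(section, subsection, required = TRUE, pattern = NA_character_)
    data.frame(section = section, subsection = subsection, required = required,
               pattern = pattern, stringsAsFactors = FALSE)
  rbind(
    # required sections
    r("PROJECT", ""), r("STUDY", ""), r("SUBJECT", ""),
    r("SUBJECT_SAMPLE_FACTORS", ""), r("COLLECTION", ""), r("TREATMENT", ""),
    r("SAMPLEPREP", ""), r("ANALYSIS", ""),
    # header block
    r(HEADER_SECTION, "STUDY_ID", TRUE, idPattern("study")),
    r(HEADER_SECTION, "ANALYSIS_ID", TRUE, idPattern("analysis")),
    r(HEADER_SECTION, "PROJECT_ID", TRUE, idPattern("project")),
    r(HEADER_SECTION, "VERSION", TRUE, "^[0-9]+(\\.[0-9]+)?$"),
    r(HEADER_SECTION, "CREATED_ON", TRUE, "^[0-9]{4}-[0-9]{2}-[0-9]{2}$"),
    # per-section required subsections
    r("PROJECT", "PROJECT_TITLE"), r("PROJECT", "INSTITUTE"),
    r("PROJECT", "LAST_NAME"), r("PROJECT", "FIRST_NAME"),
    r("PROJECT", "ADDRESS"), r("PROJECT", "EMAIL"), r("PROJECT", "PHONE"),
    r("STUDY", "STUDY_TITLE"), r("STUDY", "INSTITUTE"),
    r("STUDY", "LAST_NAME"), r("STUDY", "FIRST_NAME"),
    r("SUBJECT", "SUBJECT_TYPE"), r("SUBJECT", "SUBJECT_SPECIES"),
    r("COLLECTION", "COLLECTION_SUMMARY"),
    r("TREATMENT", "TREATMENT_SUMMARY"),
    r("SAMPLEPREP", "SAMPLEPREP_SUMMARY"),
    r("ANALYSIS", "ANALYSIS_TYPE", TRUE, "^(MS|NMR)$"),
    # the five attributes newly required in CHROMATOGRAPHY
    r("CHROMATOGRAPHY", "CHROMATOGRAPHY_TYPE"),
    r("CHROMATOGRAPHY", "INSTRUMENT_NAME"),
    r("CHROMATOGRAPHY", "COLUMN_NAME"),
    r("CHROMATOGRAPHY", "SOLVENT_A"),
    r("CHROMATOGRAPHY", "SOLVENT_B"),
    # analytical sections (rules apply when the section is present)
    r("MS", "INSTRUMENT_NAME"), r("MS", "INSTRUMENT_TYPE"),
    r("MS", "MS_TYPE"),
    r("MS", "ION_MODE", TRUE, "^(POSITIVE|NEGATIVE|UNSPECIFIED)$"),
    r("MS", "CAPILLARY_VOLTAGE", FALSE, "^-?[0-9]+(\\.[0-9]+)?( ?k?V)?$"),
    r("NM", "INSTRUMENT_NAME"), r("NM", "INSTRUMENT_TYPE"),
    r("NM", "NMR_EXPERIMENT_TYPE"),
    r("NM", "SPECTROMETER_FREQUENCY", FALSE, "^[0-9]+(\\.[0-9]+)?( ?MHz)?$")
  )
}

#' Read / write a schema rule table
#'
#' Tab-separated, one record per rule, columns `section`, `subsection`,
#' `required`, `pattern` (blank for none).
#'
#' @param path File path.
#' @return For `readSchemaRules`, the rules data frame.
#' @export
readSchemaRules <- function(path) {
  df <- utils::read.delim(path, stringsAsFactors = FALSE, na.strings = NULL)
  df$required <- as.logical(df$required)
  df$pattern[!nzchar(df$pattern)] <- NA_character_
  df
}

#' @rdname readSchemaRules
#' @param rules Rules data frame.
#' @export
writeSchemaRules <- function(rules, path) {
  rules$pattern[is.na(rules$pattern)] <- ""
  utils::write.table(rules, path, sep = "\t", row.names = FALSE, quote = FALSE)
  invisible(path)
}

# Value of a subsection within a section for schema purposes.
# Returns list(state = absent|null|blank|value, value = chr)
subsectionState <- function(doc, section, subsection) {
  blk <- getSection(doc, section)
  if (is.null(blk) || !is(blk, "KeyValueBlock"))
    return(list(state = "absent", value = NA_character_))
  if (!mapHas(blk@items, subsection))
    return(list(state = "absent", value = NA_character_))
  v <- mapGet(blk@items, subsection)[[1]]
  if (is.null(v) || (length(v) == 1 && is.na(v)))
    return(list(state = "null", value = NA_character_))
  v <- if (is.list(v)) cellText(v[[1]]) else cellText(v)
  if (!nzchar(trimws(v))) return(list(state = "blank", value = v))
  list(state = "value", value = v)
}

#' Structural validation against the mwTab schema rules
#'
#' Checks required sections/subsections and constrained value spaces,
#' producing one condensed message per distinct (section, subsection,
#' failure kind). The three failure kinds -- missing required subsection,
#' null/blank required value, and value-space violation -- are worded
#' distinctly: real depositions represent "no data" both by omitting a key
#' and by a null value, and the two deserve different fixes. All messages
#' carry check ID 24, severity error, category `format` (value-space
#' violations additionally `value`). Never raises on a parsable document.
#'
#' @param doc A [MWTabDocument-class].
#' @param rules Schema rule table; see [defaultSchemaRules()].
#' @return Validation message data frame (see [validateDocument()]).
#' @export
validateStructure <- function(doc, rules = defaultSchemaRules()) {
  msgs <- emptyMessages()
  isJson <- sourceFormat(doc) == "json"
  word <- function(x) if (isJson) x[2] else x[1]
  secRules <- rules[rules$subsection == "" & rules$required, , drop = FALSE]
  for (i in seq_len(nrow(secRules))) {
    s <- secRules$section[i]
    if (is.null(getSection(doc, s)))
      msgs <- addMessage(msgs, 24, section = s, subsection = "",
        message = sprintf("required %s %s is missing",
                          word(c("section", "top-level key")), s))
  }
  subRules <- rules[rules$subsection != "", , drop = FALSE]
  for (i in seq_len(nrow(subRules))) {
    s <- subRules$section[i]; k <- subRules$subsection[i]
    if (is.null(getSection(doc, s))) next
    st <- subsectionState(doc, s, k)
    if (subRules$required[i] && st$state == "absent") {
      msgs <- addMessage(msgs, 24, section = s, subsection = k,
        message = sprintf("required %s %s is not present in the %s section",
                          word(c("subsection", "key")), k, s))
    } else if (subRules$required[i] && st$state %in% c("null", "blank")) {
      msgs <- addMessage(msgs, 24, section = s, subsection = k,
        message = sprintf("required %s %s in section %s is %s",
                          word(c("subsection", "key")), k, s,
                          if (st$state == "null") "null valued" else "blank"))
    } else if (!is.na(subRules$pattern[i]) && st$state == "value" &&
               !grepl(subRules$pattern[i], st$value)) {
      msgs <- addMessage(msgs, 24, section = s, subsection = k,
        categories = c("format", "value"),
        message = sprintf(
          "value '%s' of %s in section %s does not match the expected form (%s)",
          st$value, k, s, subRules$pattern[i]))
    }
  }
  msgs
}
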