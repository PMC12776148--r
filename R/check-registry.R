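#' @include column-matching.R
NULL

#' The validation check registry
#'
#' One record per check ID 1--36: short name, severity, category tags and
#' the source formats the check applies to. Severities and categories are
#' declared data (the registry can be amended without touching check code):
#' warnings are the advisory / heuristic checks
#' \{15, 17, 18, 19, 20, 28, 31\}; everything else is an error. Category
#' tags: `consistency` -- two places that must carry the same data disagree;
#' `value` -- a value is incorrect; `format` -- the file violates the mwTab
#' specification. Checks 1, 2, 3, 8 and 30 can only arise from mwTab flat
#' text (duplicate keys and header/row mismatches collapse in JSON objects);
#' check 25 can only arise from JSON rows (mwTab rows are harmonized against
#' the header while parsing).
#'
#' @return Data frame with columns `id`, `short_name`, `severity`,
#'   `categories` (comma-joined), `applicability`.
#' @export
checkRegistry <- function() {
  shortNames <- c(
    "Duplicate Sub-section", "Bad Headers", "Factor Mismatch",
    "Duplicate Sample ID in SSF", "Duplicate Factors in SSF",
    "Duplicate Additional Data", "Missing Sample ID(s) in SSF",
    "Duplicate Samples in DATA", "Metabolite(s) in DATA not METABOLITES",
    "Blank Metabolite(s) in DATA", "Duplicate Metabolite(s) in DATA",
    "Metabolite(s) in METABOLITES not DATA",
    "Blank Metabolite(s) in METABOLITES",
    "Duplicate Metabolite(s) in METABOLITES", "Standard Column Name Match",
    "METABOLITES Bad Standard Values", "Missing Implied Column",
    "Paired Columns Value Mismatch", "\"other_id\" Column",
    "Multiple Standard Name Match", "Missing \"sample_id\" in EXTENDED",
    "Missing Sample ID(s) in EXTENDED", "Bad Metabolite Name",
    "JSON Schema Error", "Inconsistent Columns", "Column With No Name",
    "Null Column", "Possible Bad Column Values", "Duplicate Rows",
    "Duplicate Column Names", "Multiple Polarities", "No MS or NM Section",
    "Missing METABOLITES Section", "Missing Header",
    "Blank Sample ID(s) in EXTENDED", "Blank Metabolite(s) in EXTENDED")
  warnings <- c(15, 17, 18, 19, 20, 28, 31)
  consistency <- c(3, 7, 9, 12, 17, 18, 22)
  formatIds <- c(1, 2, 21, 24, 25, 26, 30, 32, 33, 34)
  mwtabOnly <- c(1, 2, 3, 8, 30)
  jsonOnly <- 25
  ids <- 1:36
  data.frame(
    id = ids,
    short_name = shortNames,
    severity = ifelse(ids %in% warnings, "warning", "error"),
    categories = vapply(ids, function(i) {
      tags <- c(if (i %in% consistency) "consistency",
                if (i %in% formatIds) "format")
      if (is.null(tags)) tags <- "value"
      paste(tags, collapse = ",")
    }, character(1)),
    applicability = ifelse(ids %in% mwtabOnly, "mwtab",
                           ifelse(ids %in% jsonOnly, "json", "both")),
    stringsAsFactors = FALSE)
}

checkRegistryCache <- new.env(parent = emptyenv())

getCheckRegistry <- function() {
  if (is.null(checkRegistryCache$reg)) checkRegistryCache$reg <- checkRegistry()
  checkRegistryCache$reg
}

# ---- message container -----------------------------------------------------

emptyMessages <- function() {
  data.frame(id = integer(0), short_name = character(0), severity = character(0),
             categories = character(0), section = character(0),
             subsection = character(0), message = character(0),
             occurrences = integer(0), stringsAsFactors = FALSE)
}

addMessage <- function(msgs, id, section = "", subsection = "", message = "",
                       categories = NULL, severity = NULL, occurrences = 1L) {
  reg <- getCheckRegistry()
  row <- reg[reg$id == id, , drop = FALSE]
  shortName <- if (nrow(row)) row$short_name else "Internal Validation Error"
  if (is.null(severity)) severity <- if (nrow(row)) row$severity else "error"
  if (is.null(categories)) categories <- if (nrow(row)) row$categories else "format"
  categories <- paste(categories, collapse = ",")
  rbind(msgs, data.frame(
    id = as.integer(id), short_name = shortName, severity = severity,
    categories = categories, section = section, subsection = subsection,
    message = message, occurrences = as.integer(occurrences),
    stringsAsFactors = FALSE))
}

#' Does a validation message carry a category tag?
#'
#' @param messages Validation message data frame.
#' @param category `"format"`, `"value"` or `"consistency"`.
#' @return Logical vector, one element per message.
#' @export
messageHasCategory <- function(messages, category) {
  vapply(strsplit(messages$categories, ",", fixed = TRUE),
         function(x) category %in% x, logical(1))
}

# Abbreviated listing of offending names for message text.
nameList <- function(x, max = 5) {
  x <- as.character(x)
  shown <- utils::head(x, max)
  txt <- paste(shown, collapse = ", ")
  if (length(x) > max) txt <- paste0(txt, ", ... (", length(x), " total)")
  txt
}
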