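#' @include fileio.R
NULL

formatDocument <- function(doc, format) {
  switch(format, mwtab = formatMWTab(doc), json = formatMWTabJSON(doc),
         stop("unknown format: ", format))
}

parseDocument <- function(text, format, force = FALSE) {
  switch(format, mwtab = parseMWTab(text),
         json = parseMWTabJSON(text, force = force),
         stop("unknown format: ", format))
}

#' Convert one analysis file between formats
#'
#' Reads the input (format detected by content), re-serializes it in the
#' target format and writes it next to `output` (directories created as
#' needed). Converting a file to its own format is a normalization pass.
#' The converted output parses cleanly and is consistent with the input's
#' model under [compareDocuments()].
#'
#' @param input Path to an mwTab or JSON analysis file.
#' @param to Target format, `"mwtab"` or `"json"`.
#' @param output Output path; default swaps the extension
#'   (`.txt` for mwTab, `.json` for JSON) in `outputDir` or the input's
#'   directory.
#' @param outputDir Directory for the default output path.
#' @param force Passed to the JSON reader.
#' @return The output path, invisibly.
#' @export
convertFile <- function(input, to = c("json", "mwtab"), output = NULL,
                        outputDir = NULL, force = FALSE) {
  to <- match.arg(to)
  doc <- readMWTabAny(input, force = force)
  if (is.null(output)) {
    base <- sub("\\.(txt|json|tsv)$", "", basename(input))
    dir <- if (is.null(outputDir)) dirname(input) else outputDir
    output <- file.path(dir, paste0(base, if (to == "json") ".json" else ".txt"))
  }
  writeFileUTF8(formatDocument(doc, to), output)
  invisible(output)
}

#' Round-trip a document through a chain of serializations
#'
#' Serializes and re-parses the document along `chain` (e.g.
#' `c("json", "mwtab")` writes JSON, reads it, writes mwTab, reads it) and
#' reports whether the final model is consistent with the start. Any
#' intermediate parse failure is reported as a lossy trip with the error
#' recorded, not raised.
#'
#' @param doc A [MWTabDocument-class].
#' @param chain Non-empty character vector of formats
#'   (`"mwtab"` / `"json"`).
#' @return List with `path` (chain descriptor), `lossless` flag and
#'   `differences` (data frame from [compareDocuments()], or the parse error
#'   message as an attribute).
#' @export
roundtripCheck <- function(doc, chain) {
  if (length(chain) == 0) stop("chain must name at least one format")
  stopifnot(all(chain %in% c("mwtab", "json")))
  current <- doc
  err <- NULL
  for (fmt in chain) {
    current <- tryCatch(parseDocument(formatDocument(current, fmt), fmt),
                        error = function(e) { err <<- e; NULL })
    if (!is.null(err)) break
  }
  path <- paste(c(sourceFormat(doc), chain), collapse = " -> ")
  if (!is.null(err)) {
    diffs <- newDifference("DATA", path,
                           paste("round trip parse failure:", conditionMessage(err)))
    return(list(path = path, lossless = FALSE, differences = diffs))
  }
  diffs <- compareDocuments(doc, current)
  list(path = path, lossless = nrow(diffs) == 0, differences = diffs)
}
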