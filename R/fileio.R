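#' @include table-matrix.R
NULL

#' Detect the format of an analysis file
#'
#' Content-based: a file whose first non-whitespace character is `{` is
#' JSON, otherwise mwTab flat text.
#'
#' @param path File path.
#' @return `"json"` or `"mwtab"`.
#' @export
detectFormat <- function(path) {
  text <- readFileUTF8(path)
  first <- sub("^\\s+", "", text)
  if (startsWith(first, "{")) "json" else "mwtab"
}

#' Read an analysis file in either format
#'
#' @param path File path (format detected by content).
#' @param force Passed to [readMWTabJSON()] for JSON inputs.
#' @return A [MWTabDocument-class].
#' @export
readMWTabAny <- function(path, force = FALSE) {
  if (detectFormat(path) == "json") readMWTabJSON(path, force = force)
  else readMWTab(path)
}

#' Process many inputs with per-input error recovery
#'
#' Applies `FUN` to every input; a failing input never aborts the batch.
#' Parse refusals, write failures and other errors are captured per input.
#'
#' @param inputs Character vector (paths) or list of inputs.
#' @param FUN Function of one input (a read / convert / validate closure).
#' @param outputDir Optional output directory, created (with parents) when
#'   absent before the batch runs.
#' @return Data frame with one record per input: `input`, `outcome`
#'   (`ok`, `parse_error`, `write_error` or `skipped`) and `detail`.
#' @export
processBatch <- function(inputs, FUN, outputDir = NULL) {
  if (!is.null(outputDir) && !dir.exists(outputDir))
    dir.create(outputDir, recursive = TRUE)
  n <- length(inputs)
  out <- data.frame(input = character(n), outcome = character(n),
                    detail = character(n), stringsAsFactors = FALSE)
  for (i in seq_len(n)) {
    inp <- if (is.list(inputs)) inputs[[i]] else inputs[i]
    out$input[i] <- if (is.character(inp)) inp else sprintf("input %d", i)
    res <- tryCatch(
      list(outcome = "ok", detail = {
        v <- FUN(inp)
        if (is.character(v) && length(v) == 1) v else ""
      }),
      mwtab_parse_error = function(e)
        list(outcome = "parse_error", detail = conditionMessage(e)),
      error = function(e) {
        cls <- if (grepl("cannot open|No such file|unwritable|permission",
                         conditionMessage(e), ignore.case = TRUE))
          "write_error" else "parse_error"
        list(outcome = cls, detail = conditionMessage(e))
      })
    out$outcome[i] <- res$outcome
    out$detail[i] <- res$detail
  }
  out
}
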