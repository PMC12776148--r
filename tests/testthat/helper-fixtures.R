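# Session-scoped fixture cache: generation is deterministic, so one copy per
# parameter set is enough for the whole suite.
.fixtureCache <- new.env(parent = emptyenv())

cachedFixture <- function(seed = 1, nSamples = 6, nMetabolites = 12,
                          mode = "MS", includeExtended = FALSE) {
  key <- paste(seed, nSamples, nMetabolites, mode, includeExtended)
  if (is.null(.fixtureCache[[key]]))
    .fixtureCache[[key]] <- generateFixture(seed = seed, nSamples = nSamples,
                                            nMetabolites = nMetabolites,
                                            mode = mode,
                                            includeExtended = includeExtended)
  .fixtureCache[[key]]
}

# A document with a known defect, parsed back from its serialized form.
defectiveDocument <- function(id, format = "mwtab", ...) {
  d <- injectDefect(id, format, ...)
  mwtabr:::parseDocument(d$text, d$format)
}

writeTempFixture <- function(fix, format = c("mwtab", "json"), dir = tempdir()) {
  format <- match.arg(format)
  path <- tempfile(tmpdir = dir,
                   fileext = if (format == "json") ".json" else ".txt")
  writeLines(sub("\n$", "", if (format == "json") fix$json else fix$mwtab),
             path, useBytes = TRUE)
  path
}
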