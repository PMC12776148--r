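Package: mwtabr
Title: Parsing, Validation and Conversion of Metabolomics Workbench mwTab and JSON Files
Version: 1.0.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Reads, writes, converts and validates Metabolomics Workbench
    analysis deposition files in both the mwTab flat-text format and its JSON
    twin. The package keeps duplicate keys without losing data, applies an
    error-tolerant tokenizer that repairs common tab-placement defects while
    refusing genuinely ambiguous records, runs a categorized 36-check
    validation suite plus structural schema validation, harmonizes
    depositor-chosen METABOLITES column names against a registry of 56
    standard column finders, and compares the mwTab-origin and JSON-origin
    parses of one analysis with a six-category consistency report. A seeded
    synthetic fixture generator with per-check defect injection supports
    testing without repository downloads.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    methods,
    jsonlite,
    stats,
    utils
Suggests: testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Collate:
    'AllGenerics.R'
    'AllClasses.R'
    'DuplicatesMap-methods.R'
    'MWTabDocument-methods.R'
    'tokenizer.R'
    'read-mwtab.R'
    'write-mwtab.R'
    'json-io.R'
    'consistency.R'
    'table-matrix.R'
    'fileio.R'
    'converter.R'
    'schema.R'
    'column-registry.R'
    'column-matching.R'
    'check-registry.R'
    'validator.R'
    'fixtures.R'
    'defects.R'
    'cli.R'
    'mwtabr-package.R'
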