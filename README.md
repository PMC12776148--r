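# mwtabr

Parsing, validation, conversion and consistency checking for Metabolomics
Workbench analysis deposition files, in both the **mwTab** flat-text format
(`#SECTION` headers, prefixed `CODE:KEY<TAB>VALUE` item lines, fenced
tab-delimited tables) and its **JSON** twin.

The Metabolomics Workbench hosts thousands of MS and NMR analyses deposited
by hundreds of labs, and the files show every defect that hand-assembled
flat text can have: duplicated keys and columns, missing or surplus tabs,
bogus section lines, mixed null/absent conventions, non-standard
METABOLITES column names. `mwtabr` is written for curators and for anyone
attempting large-scale reuse of those depositions. Its core commitments:

* **Lossless, duplicate-key-preserving parsing.** The in-memory model is
  built on an ordered key/value container that retains repeated keys
  (`DuplicatesMap`), so a table with two `S1` columns keeps both, in order,
  through any chain of read/write cycles in either format. The JSON writer
  emits repeated object members itself, because standard JSON writers
  refuse to.
* **Error-tolerant tokenizing with honest refusal.** Rows are harmonized
  against their header (trailing empty cells dropped, missing trailing tabs
  padded) and oddities are recorded as parse annotations; genuinely
  ambiguous records — an extra `=` or `:` in a SUBJECT_SAMPLE_FACTORS
  field, a missing tab after a section code, a value with an embedded
  carriage return — are refused with classed errors rather than guessed at.
* **A categorized 36-check validation suite** plus structural schema
  validation (required sections/subsections, accession patterns
  `ST\d{6}` / `AN\d{6}` / `PR\d{6}`, constrained value spaces). Every
  finding carries a check ID, short name, severity (warning/error) and
  category tags (`format`, `value`, `consistency`); files classify as
  *Passing*, *Warnings Only* or *Errors*.
* **Standard-column harmonization.** A declarative registry of 56
  `ColumnFinder`s maps depositor spellings (`ret time`, `m/z`, `KEGG`) to
  canonical METABOLITES column names and validates column values
  (e.g. KEGG IDs must look like `C00031`).
* **Cross-format consistency comparison** with six difference categories
  (`DATA`, `SSF`, `SectionKeys`, `SubsectionKeys`, `SubsectionValues`,
  `SubsectionType`).
* **A seeded synthetic generator** of valid analyses with per-check defect
  injection, so the whole toolchain is testable without repository
  downloads.

## A worked example

```r
library(mwtabr)

fix <- generateFixture(seed = 1, nSamples = 6, nMetabolites = 12)
headerFields(fix$document)
#>     STUDY_ID  ANALYSIS_ID   PROJECT_ID      VERSION   CREATED_ON
#>   "ST876874"   "AN454473"   "PR960213"          "1" "2025-10-01"

# a clean fixture validates Passing
categorizeMessages(validateDocument(fix$document))$status
#> [1] "Passing"

# break it: corrupt one KEGG ID in the METABOLITES table (defect 16)
msgs <- validateDocument(mwtabr:::parseDocument(
  injectDefect(16, "mwtab", seed = 1)$text, "mwtab"))
msgs[, c("id", "short_name", "severity", "section", "subsection")]
#>   id                      short_name severity     section subsection
#> 1 16 METABOLITES Bad Standard Values    error METABOLITES    kegg_id
```

The message data frame is the machine-readable contract: one condensed
record per root cause with an occurrence count, serializable to JSON via
the CLI.

Round-trip and conversion guarantees:

```r
roundtripCheck(fix$document, c("json", "mwtab", "json"))$lossless
#> [1] TRUE
jsonDoc <- parseMWTabJSON(formatMWTabJSON(fix$document))
nrow(compareDocuments(fix$document, jsonDoc))
#> [1] 0
```

## Command line

```sh
Rscript inst/scripts/mwtab-cli.R validate --json-output report.json AN000001.txt
Rscript inst/scripts/mwtab-cli.R convert --to json --output-dir out/ *.txt
Rscript inst/scripts/mwtab-cli.R compare AN000001.txt AN000001.json
Rscript inst/scripts/mwtab-cli.R generate --seed 7 --output-dir fixtures/
```

Exit codes: 0 all Passing/consistent, 1 findings, 2 parse failures.
Batches always continue past failing files.

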