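---
title: "Lossless parsing and categorized validation of Metabolomics Workbench files"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Lossless parsing and categorized validation of Metabolomics Workbench files}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(mwtabr)
```

# The problem

A Metabolomics Workbench analysis is distributed as two text files that are
supposed to carry the same information: an mwTab flat-text file and a JSON
file. Both are assembled, ultimately, from depositor input, and real files
mix conventions freely: a "missing" value may be an absent key, a key with a
null value, or an empty string; tables gain or lose tabs at row ends;
columns and keys get duplicated; `#FACTORS` lines appear where no section of
that name exists; METABOLITES columns are named `ret time`, `m/z` or `KEGG`
instead of their standard names. Tools that assume clean input either crash,
or — worse — silently drop data (a mapping container that forbids duplicate
keys keeps only the last `S1` column it sees).

`mwtabr` takes the opposite stance on both failure modes:

* anything *representable* is preserved exactly (duplicate keys included),
  so that read → write → read is a fixed point in either format;
* anything *ambiguous* is refused with a classed error rather than guessed
  at, because a wrong guess corrupts the record invisibly.

# The data model

A document is an ordered map of sections. Three content shapes exist:
key/value blocks, the SUBJECT_SAMPLE_FACTORS record list, and tables. All
ordered maps are `DuplicatesMap` objects — parallel key and value sequences
in insertion order, with `mapGet()` returning *all* values for a key and
`mapGetOne()` erroring on duplicates so that callers must confront
duplication explicitly.

Three deliberate modelling choices:

* **Absent key, empty value and null value are three distinct states.**
  Depositions genuinely mix the first two conventions, and the structural
  validator words its findings differently for each, because each needs a
  different fix.
* **Cells are text.** Numeric interpretation happens only inside
  validators; `"1.0"` and `"1"` are different values, because losslessness
  is the product's promise and typed convenience would destroy it.
* **The header block is a section.** The `METABOLOMICS WORKBENCH`
  attributes (VERSION, CREATED_ON, STUDY_ID, ANALYSIS_ID, PROJECT_ID) are
  stored as the first section and surfaced via `headerFields()`; the
  consistency comparator then treats the header as an ordinary
  pseudo-section for free.

Row and column indices are 1-based everywhere, matching both R idiom and
the line numbers users see in their files.

# Tokenizing and repairs

The tokenizer classifies each physical line (section header, prefixed item,
SSF line, table fence, table row) and applies exactly two *repairs*, both of
which reflect observed tab damage in real tables: trailing empty cells
beyond the header are dropped, and rows shorter than the header are padded
with empty text. Both are recorded per row; a row whose *non-empty* cells
overflow the header is additionally recorded and fires the bad-headers
check. Harmonization is idempotent.

Everything else is a refusal, with a 1-based line number and a condition
class per defect family:

* a section-code line without its tab separator;
* an uncapitalized, prefix-less line outside a table — the footprint of a
  value containing an embedded carriage return;
* an SSF factors fragment with zero or two-plus `:` separators, or an
  additional-data fragment without exactly one `=` (a missing `;` between
  pairs collapses two pairs into one fragment with two `=`);
* a repeated `*_DATA_END` fence with rows between;
* on the JSON side: malformed JSON, non-object table rows (rescuable with
  `force = TRUE`, which skips them with a warning), and duplicate keys at
  the *top* level, which cannot be attributed to sections and are therefore
  not supported (below the top level they are preserved faithfully).

A `#FACTORS` header — or any out-of-vocabulary section — is *not* a
refusal: the section is created, kept empty, and flagged in the parse
annotations. This choice makes the cross-format comparator attribute the
resulting discrepancy to `SectionKeys`, where it belongs. The known
pathological consequence (a later prefixed line swallowed into the bogus
section re-serializes without its prefix and then fails to re-parse) is
deliberately not special-cased; repairing bad lines is a curation task, out
of scope for a faithful parser.

UTF-8 is required; undecodable bytes are an error rather than a silent
transcoding.

# Serialization and round trips

Writers emit sections and subsections in one predefined order (the
specification's presentation order), so serialization is byte-deterministic:
writing the same document twice gives identical bytes, and write → read →
write is a byte fixed point. The JSON writer is hand-rolled for one reason:
standard writers cannot emit duplicate object members, and duplicate-member
output is precisely the point.

The JSON layout nests the METABOLITES and EXTENDED tables (and, when the
document carries one, the `Factors` preamble row) inside their data
composite. Including the factors row in our own JSON is what makes
mwTab → JSON → mwTab lossless; repository-downloaded JSON lacks it, so the
comparator compares factors rows only when both documents carry one.

`roundtripCheck()` states the contract operationally: for any generated
fixture, all four one-step chains (mwTab→mwTab, mwTab→JSON, JSON→mwTab,
JSON→JSON) and arbitrary compositions of them reproduce the starting model.

# The consistency comparator

`compareDocuments()` tags every discrepancy with one of six categories:
`SectionKeys`, `SubsectionKeys`, `SubsectionValues`, `SubsectionType`
(same subsection, different value *shape* — scalar vs list), `DATA`
(anything inside the tables) and `SSF` (anything inside the record list).
Key/value blocks compare with dictionary semantics (key multisets, ordered
value lists per key); table rows and columns compare order-sensitively,
because files are ordered artifacts and losslessness is claimed over them.
Consistency of a conversion is a theorem of the implementation — the
converter and comparator are exercised together over seeded fixtures in the
test suite — not an aspiration.

# Validation

`validateDocument()` runs 36 registered checks plus structural schema
validation and returns a data frame, one condensed message per (check,
section, column-or-subsection) root cause with an occurrence count.
Messages carry severity, category tags (`format`, `value`, `consistency`)
and wording chosen for the source format (tabular files have subsections
and header rows; JSON files have keys and objects). `categorizeMessages()`
folds a message list into the *Passing* / *Warnings Only* / *Errors* status
with per-category error flags. Validation never raises on a parsable
document: each check group runs under a catch-all that converts an internal
failure into a reported message, and a fuzzing test holds the whole suite
to that.

Decisions worth recording:

* **Severities are declared data.** Only the standard-column rename check
  is unambiguously documented as always-warning; we additionally classify
  the heuristic or advisory checks (implied partners, paired-value
  alignment, `other_id` presence, multi-match, near-constant columns, mixed
  polarity) as warnings and everything else as errors. The registry is a
  table, so reclassification is a data edit.
* **Applicability.** Duplicate subsections, bad headers, factor mismatches,
  duplicate sample columns and duplicate column names can only arise from
  flat text (JSON objects collapse them); inconsistent per-row column sets
  can only arise from JSON (harmonization makes mwTab rows rectangular).
  The registry records this per check, and the defect injector covers
  exactly the applicable (check, format) pairs.
* **The near-constant-column check** fires when the modal non-empty value
  covers at least 90% but less than 100% of a column's non-empty cells,
  with a minimum of 10 non-empty cells. The 90% threshold is the documented
  convention; the minimum length is ours, to keep the heuristic silent on
  tables too small for a 90% share to mean anything.
* **The structural schema is a rule table** (section, subsection, required,
  value pattern), not code, because the upstream specification drifts and
  old versions are unavailable; a corrected requirement list is a data
  edit. The five CHROMATOGRAPHY attributes promoted to required in the
  2023-08-01 update default to CHROMATOGRAPHY_TYPE, INSTRUMENT_NAME,
  COLUMN_NAME, SOLVENT_A and SOLVENT_B — the section's headline fields —
  since the specification names the count but not the list.
* **Accession patterns** `ST\d{6}` / `AN\d{6}` / `PR\d{6}` follow the
  universal Workbench accession convention.

# Column matching

The 56-entry finder registry maps observed METABOLITES column spellings to
canonical names. Matching is rule-per-finder — a shared normalization
(lowercase, separators collapsed to `_`) plus anchored alternation patterns
per finder — rather than a global edit-distance cutoff: fuzziness lives in
each finder's own rules, where false positives can be tuned away
name-by-name. Multi-matches (e.g. a bare `retention`, ambiguous between
retention time and retention index) are reported, never silently resolved.
Only the identifier-bearing canonicals named in the repository's own
conventions are load-bearing (moverz_quant, retention_time,
retention_index/_type, kegg_id, other_id/_type, lab_id, polarity,
sample_id, the `Metabolite` anchor); the remainder of the registry is
drawn from common METABOLITES metadata and is explicitly provisional,
declarative data — `readColumnRegistry()` / `writeColumnRegistry()` load
and save it as a config file. Value rules are syntactic only (a KEGG ID
must look like one); no online identifier resolution is attempted.

# The synthetic generator

`generateFixture()` is the package's test bed: a seeded, deterministic
generator of internally consistent analyses (byte-identical output for
identical parameters). It emulates the *shape* of depositions — accessions,
complete metadata sections, a factor design `Treatment:{Control, Case}`,
DATA with Samples/Factors preamble, canonical METABOLITES columns with
plausible masses, retention values and KEGG IDs, optional EXTENDED table —
and deliberately not the statistics of real intensity data (values are
uniform random positives). Defaults are modest (6 samples, 12 metabolites);
the property sweeps in the test suite vary sizes from 1×1 upward across
both analytical modes. What passing tests show is therefore structural
correctness over the format's feature space, not robustness to the content
distribution of any particular repository snapshot; the defect injector
(`injectDefect()`, one recipe per applicable check/format pair, plus nine
unparsable classes in `injectParseDefect()`) is what carries the negative
cases.

# Known limitations

* Unknown sections carrying prefixed items re-serialize without a prefix
  and will not re-parse (the `#FACTORS` pathology); by design, repair is
  out of scope.
* A table with a header but zero rows loses its column list when
  serialized to JSON, which stores tables as row objects.
* The structural rule table transcribes the current specification's
  headline requirements, not every field of every historical version.
* Column-finder patterns are tuned by construction, not against the live
  repository; the registry file exists precisely so users can retune it.

# Problem sizes used in the checks

The test suite's end-to-end properties run at desk scale: 100 seeded
fixtures for the clean-pass, round-trip and converter-consistency sweeps,
the full defect matrix (one injection per applicable check/format pair),
and 1000 random text mutations for the crash-freedom fuzz, with fixture
sizes cycling over 1–6 samples and 1–12 metabolites. These sizes exercise
every code path the properties quantify over; the guarantees are
structural, so scale adds nothing but time.
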