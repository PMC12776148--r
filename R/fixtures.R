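#' @include validator.R
NULL

# Deterministic RNG scope: evaluate expr under the given seed and restore
# the caller's RNG state afterwards.
withSeed <- function(seed, expr) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  force(expr)
}

METABOLITE_WORDS <- c(
  "glucose", "alanine", "glutamate", "citrate", "lactate", "pyruvate",
  "succinate", "fumarate", "malate", "serine", "glycine", "leucine",
  "isoleucine", "valine", "threonine", "proline", "tyrosine", "tryptophan",
  "phenylalanine", "methionine", "cysteine", "arginine", "histidine",
  "lysine", "asparagine", "glutamine", "ornithine", "taurine", "creatinine",
  "carnitine", "choline", "betaine", "inosine", "uridine", "adenosine",
  "xanthine", "hypoxanthine", "urate", "cholesterol", "sphingosine")

kvBlock <- function(...) {
  pairs <- list(...)
  dm <- DuplicatesMap()
  for (k in names(pairs)) dm <- mapAppend(dm, k, pairs[[k]])
  KeyValueBlock(items = dm)
}

#' Generate a valid synthetic analysis fixture
#'
#' Builds one internally consistent analysis -- header accessions, full
#' metadata sections, SUBJECT_SAMPLE_FACTORS, a DATA table with Samples and
#' Factors preamble rows, a METABOLITES table with canonical standard
#' columns, and optionally an EXTENDED table -- and serializes it in both
#' formats. Generated documents validate cleanly (Passing) by construction.
#' Identical arguments produce byte-identical outputs.
#'
#' Content emulates the shape of repository depositions (factor design
#' `Treatment:{Control,Case}`, uniform random positive intensities, metabolite
#' names from a fixed word list) without statistical realism of intensities.
#'
#' @param seed Integer seed driving all random content.
#' @param nSamples Number of samples (>= 1).
#' @param nMetabolites Number of metabolites (>= 1).
#' @param mode Analytical mode, `"MS"` or `"NM"`.
#' @param includeExtended Also generate an EXTENDED table.
#' @return List with `document` (the mwTab-origin [MWTabDocument-class]),
#'   `mwtab` (flat text), `json` (JSON text) and the generation parameters.
#' @export
generateFixture <- function(seed = 1, nSamples = 6, nMetabolites = 12,
                            mode = c("MS", "NM"), includeExtended = FALSE) {
  mode <- match.arg(mode)
  stopifnot(nSamples >= 1, nMetabolites >= 1)
  withSeed(seed, {
    num <- function(n, lo, hi, digits = 1) sprintf(paste0("%.", digits, "f"),
                                                   stats::runif(n, lo, hi))
    accession <- function(prefix) sprintf("%s%06d", prefix,
                                          sample.int(999999L, 1))
    samples <- sprintf("S%03d", seq_len(nSamples))
    metIdx <- sample.int(length(METABOLITE_WORDS),
                         min(nMetabolites, length(METABOLITE_WORDS)))
    metabolites <- METABOLITE_WORDS[metIdx]
    while (length(metabolites) < nMetabolites)
      metabolites <- c(metabolites,
                       paste0(METABOLITE_WORDS[(length(metabolites) %%
                                                  length(METABOLITE_WORDS)) + 1],
                              "_", length(metabolites) + 1))
    treatment <- rep(c("Control", "Case"), length.out = nSamples)

    sections <- DuplicatesMap()
    add <- function(name, content) sections <<- mapAppend(sections, name, content)

    add(HEADER_SECTION, kvBlock(
      VERSION = "1", CREATED_ON = "2025-10-01",
      STUDY_ID = accession("ST"), ANALYSIS_ID = accession("AN"),
      PROJECT_ID = accession("PR")))
    add("PROJECT", kvBlock(
      PROJECT_TITLE = sprintf("Synthetic metabolomics project %d", seed),
      INSTITUTE = "Example University", LAST_NAME = "Doe", FIRST_NAME = "Jay",
      ADDRESS = "1 Example Way", EMAIL = "jay.doe@example.org",
      PHONE = "555-0100"))
    add("STUDY", kvBlock(
      STUDY_TITLE = sprintf("Synthetic study %d", seed),
      STUDY_SUMMARY = "Synthetic fixture for format and validation testing",
      INSTITUTE = "Example University", LAST_NAME = "Doe", FIRST_NAME = "Jay"))
    add("SUBJECT", kvBlock(
      SUBJECT_TYPE = "Human", SUBJECT_SPECIES = "Homo sapiens",
      TAXONOMY_ID = "9606"))

    records <- lapply(seq_len(nSamples), function(i) {
      fac <- mapAppend(DuplicatesMap(), "Treatment", treatment[i])
      extra <- mapAppend(DuplicatesMap(), "RAW_FILE_NAME",
                         sprintf("run_%03d.raw", i))
      SSFRecord(subjectId = sprintf("SU%03d", i), sampleId = samples[i],
                factors = fac, additionalData = extra)
    })
    add("SUBJECT_SAMPLE_FACTORS", SubjectSampleFactors(records = records))

    add("COLLECTION", kvBlock(
      COLLECTION_SUMMARY = "Plasma collected after overnight fast",
      SAMPLE_TYPE = "Blood (plasma)"))
    add("TREATMENT", kvBlock(
      TREATMENT_SUMMARY = "Control vs single-dose treatment arm"))
    add("SAMPLEPREP", kvBlock(
      SAMPLEPREP_SUMMARY = "Protein precipitation with cold methanol"))
    if (mode == "MS")
      add("CHROMATOGRAPHY", kvBlock(
        CHROMATOGRAPHY_TYPE = "Reversed phase",
        INSTRUMENT_NAME = "Thermo Vanquish",
        COLUMN_NAME = "Waters Acquity BEH C18 (100 x 2.1mm, 1.7um)",
        SOLVENT_A = "100% water; 0.1% formic acid",
        SOLVENT_B = "100% acetonitrile; 0.1% formic acid"))
    add("ANALYSIS", kvBlock(
      ANALYSIS_TYPE = if (mode == "MS") "MS" else "NMR"))
    if (mode == "MS") {
      add("MS", kvBlock(
        INSTRUMENT_NAME = "Thermo Q Exactive Orbitrap",
        INSTRUMENT_TYPE = "Orbitrap", MS_TYPE = "ESI",
        ION_MODE = "POSITIVE"))
    } else {
      add("NM", kvBlock(
        INSTRUMENT_NAME = "Bruker Avance III 600",
        INSTRUMENT_TYPE = "FT-NMR", NMR_EXPERIMENT_TYPE = "1D-1H"))
    }

    dataName <- if (mode == "MS") "MS_METABOLITE_DATA" else "NMR_METABOLITE_DATA"
    dataCols <- c(CANONICAL_ANCHOR, samples)
    factorsRow <- vapply(records, function(r) serializeFactors(r@factors),
                         character(1))
    dataRows <- lapply(seq_len(nMetabolites), function(i)
      DuplicatesMap(dataCols,
                    as.list(c(metabolites[i], num(nSamples, 1000, 900000)))))
    add(dataName, MWTabTable(
      role = "DATA", units = "peak area", columns = dataCols,
      factorsRow = factorsRow, rows = dataRows))

    metCols <- c(CANONICAL_ANCHOR, "moverz_quant", "retention_time",
                 "retention_index", "retention_index_type", "kegg_id")
    metRows <- lapply(seq_len(nMetabolites), function(i)
      DuplicatesMap(metCols, as.list(c(
        metabolites[i],
        sprintf("%.4f", stats::runif(1, 70, 900)),
        sprintf("%.2f", stats::runif(1, 0.5, 18)),
        sprintf("%.0f", stats::runif(1, 100000, 900000)),
        "Fiehn RI",
        sprintf("C%05d", sample.int(99999L, 1))))))
    add("METABOLITES", MWTabTable(
      role = "METABOLITES", columns = metCols, rows = metRows))

    if (includeExtended) {
      extName <- if (mode == "MS") "EXTENDED_MS_METABOLITE_DATA"
                 else "EXTENDED_NMR_METABOLITE_DATA"
      extCols <- c(CANONICAL_ANCHOR, "sample_id", "peak_area")
      extRows <- list()
      for (i in seq_len(nMetabolites))
        for (s in samples)
          extRows[[length(extRows) + 1]] <- DuplicatesMap(
            extCols, as.list(c(metabolites[i], s, num(1, 1000, 900000))))
      add(extName, MWTabTable(role = "EXTENDED", columns = extCols,
                              rows = extRows))
    }

    doc0 <- MWTabDocument(sections = sections, sourceFormat = "mwtab")
    mwtab <- formatMWTab(doc0)
    json <- formatMWTabJSON(doc0)
    list(document = parseMWTab(mwtab), mwtab = mwtab, json = json,
         seed = seed, nSamples = nSamples, nMetabolites = nMetabolites,
         mode = mode, includeExtended = includeExtended)
  })
}
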