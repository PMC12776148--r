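#' @include schema.R
NULL

# Matching is rule-per-finder (normalization plus anchored alternation
# patterns), not edit distance: false-positive control lives in each
# finder's own rules. The named set covers the standard METABOLITES-table
# metadata columns observed across Metabolomics Workbench depositions; it is
# declarative data -- corrections are data edits, loadable from file.
columnFinderDefinitions <- function() {
  f <- function(canonical, patterns, value = character(0), partners = character(0),
                exclusive = character(0))
    ColumnFinder(canonical, patterns, value, partners, exclusive)
  num <- "^[0-9]+(\\.[0-9]+)?$"
  signedNum <- "^-?[0-9]+(\\.[0-9]+)?$"
  list(
    f("Metabolite",
      c("metabolite", "metabolite_name", "metabolite_id", "compound",
        "compound_name", "cpd_name")),
    f("moverz_quant",
      c("moverz_quant", "moverz", "m/z", "mz", "quant_mz", "quantified_m/z",
        "quantified_mz", "quant_mass", "mass_to_charge"), num),
    f("retention_time",
      c("retention_time", "ret_time", "rt", "rt_min", "retention_time_min",
        "retention"),
      "^[0-9]+(\\.[0-9]+)?( ?(s|sec|min))?$",
      exclusive = "retention_index"),
    f("retention_index",
      c("retention_index", "ret_index", "ri", "retention"), num,
      partners = "retention_index_type", exclusive = "retention_time"),
    f("retention_index_type",
      c("retention_index_type", "ri_type"), partners = "retention_index"),
    f("kegg_id", c("kegg_id", "kegg", "kegg_ids"), "^[CDGRM][0-9]{5}$"),
    f("hmdb_id", c("hmdb_id", "hmdb", "hmdb_ids"), "^HMDB[0-9]{4,7}$"),
    f("pubchem_cid",
      c("pubchem_cid", "pubchem_id", "pubchem", "cid", "pubchem_compound_id"),
      "^[0-9]+$"),
    f("pubchem_sid", c("pubchem_sid", "sid", "pubchem_substance_id"), "^[0-9]+$"),
    f("inchi_key", c("inchi_key", "inchikey"), "^[A-Z]{14}-[A-Z]{10}-[A-Z]$"),
    f("inchi", c("inchi", "inchi_code", "inchi_string"), "^InChI=1S?/.+$"),
    f("smiles", c("smiles", "smiles_code", "canonical_smiles", "smile")),
    f("cas_id",
      c("cas_id", "cas", "cas_number", "casrn", "cas_registry_number"),
      "^[0-9]{2,7}-[0-9]{2}-[0-9]$"),
    f("chebi_id", c("chebi_id", "chebi"), "^(CHEBI:)?[0-9]+$"),
    f("metlin_id", c("metlin_id", "metlin"), "^[0-9]+$"),
    f("lipidmaps_id",
      c("lipidmaps_id", "lipid_maps_id", "lipidmaps", "lm_id"),
      "^LM[A-Z]{2}[0-9A-Z]{8,10}$"),
    f("refmet_name", c("refmet_name", "refmet")),
    f("binbase_id", c("binbase_id", "binbase", "bb_id"), "^[0-9]+$"),
    f("fiehn_id", c("fiehn_id", "fiehnlib_id")),
    f("formula",
      c("formula", "molecular_formula", "chemical_formula", "elemental_formula"),
      "^([A-Z][a-z]?[0-9]*)+[+-]?$"),
    f("exact_mass",
      c("exact_mass", "monoisotopic_mass", "mono_mass", "exactmass", "mass"), num),
    f("molecular_weight", c("molecular_weight", "mol_weight", "mw", "mol_wt"), num),
    f("adduct", c("adduct", "adducts", "adduct_type", "ion_adduct")),
    f("polarity",
      c("polarity", "ion_mode", "ionization_mode", "mode", "esi_mode"),
      "^(?i)(pos(itive)?|neg(ative)?|\\+|-)$"),
    f("other_id", c("other_id", "other_ids"), partners = "other_id_type"),
    f("other_id_type", c("other_id_type", "other_id_types"),
      partners = "other_id"),
    f("lab_id", c("lab_id", "local_id", "internal_id", "in_house_id")),
    f("sample_id", c("sample_id", "sample", "sample_name", "sample_ids")),
    f("compound_class",
      c("compound_class", "class", "chemical_class", "lipid_class")),
    f("annotation_level",
      c("annotation_level", "msi_level", "identification_level", "id_level",
        "annotation_confidence"), "^[1-4]$"),
    f("theoretical_mz",
      c("theoretical_mz", "theoretical_m/z", "calc_mz", "calculated_mz",
        "expected_mz"), num),
    f("observed_mz",
      c("observed_mz", "observed_m/z", "measured_mz", "experimental_mz"), num),
    f("mass_error_ppm",
      c("mass_error_ppm", "ppm_error", "mass_error", "delta_ppm", "ppm"),
      signedNum),
    f("isotope", c("isotope", "isotope_label", "isotopologue")),
    f("charge", c("charge", "charge_state", "z"), "^[+-]?[0-9]+[+-]?$"),
    f("precursor_mz",
      c("precursor_mz", "precursor_m/z", "prec_mz", "parent_mz", "parent_ion"),
      num),
    f("product_mz",
      c("product_mz", "product_m/z", "fragment_mz", "daughter_mz",
        "product_ion"), num),
    f("collision_energy",
      c("collision_energy", "ce", "collision_energy_v", "collision_energy_ev"),
      "^[0-9]+(\\.[0-9]+)?( ?e?V)?$"),
    f("quant_ion", c("quant_ion", "quantifier_ion", "quantifier")),
    f("qualifier_ion", c("qualifier_ion", "qualifier", "confirm_ion")),
    f("internal_standard", c("internal_standard", "istd", "int_std")),
    f("spectrum_id",
      c("spectrum_id", "spectra_id", "spectrum_index", "scan_id")),
    f("chemical_shift",
      c("chemical_shift", "shift", "ppm_shift", "chemical_shift_ppm"),
      signedNum),
    f("multiplicity", c("multiplicity", "peak_multiplicity", "mult"),
      "^(?i)(s|d|t|q|m|dd|dt|td|br|singlet|doublet|triplet|quartet|multiplet)$"),
    f("assignment", c("assignment", "peak_assignment", "atom_assignment")),
    f("bin_range", c("bin_range", "bin_range_ppm", "bin", "bin_ppm")),
    f("peak_area", c("peak_area", "area", "raw_area"), num),
    f("peak_height", c("peak_height", "height", "intensity", "raw_intensity"),
      num),
    f("concentration", c("concentration", "conc", "amount")),
    f("units", c("units", "unit", "concentration_units", "conc_units")),
    f("dilution_factor", c("dilution_factor", "dilution"), num),
    f("spectra_type", c("spectra_type", "spectrum_type", "ms_level")),
    f("database_id", c("database_id", "db_id", "database_identifier")),
    f("database", c("database", "db", "source_database", "library")),
    f("score", c("score", "match_score", "msms_score", "similarity_score"),
      signedNum),
    f("comment", c("comment", "comments", "note", "notes", "remark"))
  )
}

registryCache <- new.env(parent = emptyenv())

#' The prebuilt registry of standard column finders
#'
#' A named list of [ColumnFinder-class] objects, one per standard
#' METABOLITES-table column name (56 entries). Each finder carries its
#' anchored name-matching alternatives, an optional value-validation
#' pattern, and implied-partner links (e.g. `retention_index` pairs with
#' `retention_index_type`). The registry is generic over tables: the
#' matching operations take plain header and value vectors.
#'
#' @return Named list of [ColumnFinder-class] objects.
#' @export
defaultColumnRegistry <- function() {
  if (is.null(registryCache$default)) {
    finders <- columnFinderDefinitions()
    names(finders) <- vapply(finders, function(x) x@canonical, character(1))
    registryCache$default <- finders
  }
  registryCache$default
}

#' Read / write a column-finder registry config file
#'
#' JSON, one record per finder (`canonical`, `patterns`, `valuePattern`,
#' `impliedPartners`, `exclusiveWith`), so the registry can be corrected
#' without code changes.
#'
#' @param path File path.
#' @return For `readColumnRegistry`, a named list of
#'   [ColumnFinder-class] objects.
#' @export
readColumnRegistry <- function(path) {
  recs <- jsonlite::fromJSON(readFileUTF8(path), simplifyVector = FALSE)
  finders <- lapply(recs, function(r)
    ColumnFinder(canonical = r$canonical,
                 patterns = as.character(unlist(r$patterns)),
                 valuePattern = as.character(unlist(r$valuePattern)),
                 impliedPartners = as.character(unlist(r$impliedPartners)),
                 exclusiveWith = as.character(unlist(r$exclusiveWith))))
  names(finders) <- vapply(finders, function(x) x@canonical, character(1))
  finders
}

#' @rdname readColumnRegistry
#' @param registry Named list of [ColumnFinder-class] objects.
#' @export
writeColumnRegistry <- function(registry, path) {
  recs <- lapply(unname(registry), function(fdr) list(
    canonical = fdr@canonical, patterns = as.list(fdr@patterns),
    valuePattern = as.list(fdr@valuePattern),
    impliedPartners = as.list(fdr@impliedPartners),
    exclusiveWith = as.list(fdr@exclusiveWith)))
  writeFileUTF8(as.character(
    jsonlite::toJSON(recs, auto_unbox = TRUE, pretty = TRUE)), path)
  invisible(path)
}
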