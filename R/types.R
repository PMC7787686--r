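# Domain tables. Collections are plain data.frames with validated columns,
# so that they round-trip through the delimited interchange formats.

#' Construct a proband table
#'
#' One row per patient. Set-valued fields (tumor flags, phenotype flags,
#' chromosomal events) are comma-joined strings; use [has_flag()] to query
#' them.
#'
#' @param patient_id Character patient identifiers (unique).
#' @param sex `"male"` or `"female"`.
#' @param age_at_diagnosis Integer years, 0-17.
#' @param diagnosis Diagnosis term.
#' @param tumor_flags,phenotype_flags,chromosomal_events Comma-joined flag
#'   sets (may be empty strings).
#' @param feedback_level Feedback level chosen by the family (1, 2 or 3).
#' @param family_id Pedigree identifier (defaults to the patient id).
#' @return A `data.frame` with an added `diagnosis_group` column.
#' @export
proband_table <- function(patient_id, sex, age_at_diagnosis, diagnosis,
                          tumor_flags = "", phenotype_flags = "",
                          chromosomal_events = "", feedback_level = 3L,
                          family_id = patient_id) {
  df <- data.frame(patient_id = as.character(patient_id),
                   family_id = as.character(family_id),
                   sex = as.character(sex),
                   age_at_diagnosis = as.integer(age_at_diagnosis),
                   diagnosis = as.character(diagnosis),
                   tumor_flags = as.character(tumor_flags),
                   phenotype_flags = as.character(phenotype_flags),
                   chromosomal_events = as.character(chromosomal_events),
                   feedback_level = as.integer(feedback_level),
                   stringsAsFactors = FALSE)
  df$diagnosis_group <- diagnosis_group(df$diagnosis)
  validate_probands(df)
}

validate_probands <- function(df) {
  stopifnot(is.data.frame(df))
  req <- c("patient_id", "sex", "age_at_diagnosis", "diagnosis",
           "diagnosis_group", "feedback_level")
  miss <- setdiff(req, names(df))
  if (length(miss)) stop("proband table missing column(s): ",
                         paste(miss, collapse = ", "))
  if (anyDuplicated(df$patient_id)) stop("duplicate patient_id in proband table")
  if (any(!df$sex %in% .sex_levels)) stop("sex must be male or female")
  if (any(df$age_at_diagnosis < 0 | df$age_at_diagnosis > 17)) {
    stop("age_at_diagnosis must lie in [0, 17]")
  }
  if (any(!df$feedback_level %in% 1:3)) stop("feedback_level must be 1, 2 or 3")
  bad <- setdiff(unlist(string_to_flags(df$chromosomal_events)),
                 .chromosomal_events)
  if (length(bad)) stop("unknown chromosomal event(s): ",
                        paste(bad, collapse = ", "))
  df
}

#' Construct a family (pedigree) table
#'
#' One row per cancer event; relatives without cancer appear as a single row
#' with `diagnosis = NA`. Lineage must be `"not_applicable"` for first-degree
#' relations and maternal/paternal otherwise.
#'
#' @param family_id,relative_id Identifiers.
#' @param relation Relation term (canonical vocabulary or common synonyms,
#'   see [relation_degrees()]).
#' @param lineage `"maternal"`, `"paternal"` or `"not_applicable"`.
#' @param diagnosis Cancer diagnosis (NA for cancer-free relatives).
#' @param age_at_diagnosis Age of the relative at that diagnosis.
#' @param known_at_proband_diagnosis Whether the event was already known
#'   when the proband was diagnosed (criteria only use known events).
#' @param verification Verification status of the event.
#' @param malignant Whether the event is a malignancy (benign tumors are
#'   recorded but never counted by the clinical criteria).
#' @param consanguineous Family-level consanguinity flag.
#' @param known_cps Family-level flag: a CPS is already known in the family.
#' @return A validated `data.frame` with a `degree` column added.
#' @export
family_table <- function(family_id, relative_id, relation, lineage,
                         diagnosis = NA_character_,
                         age_at_diagnosis = NA_real_,
                         known_at_proband_diagnosis = TRUE,
                         verification = "reported_only",
                         malignant = TRUE,
                         consanguineous = FALSE,
                         known_cps = FALSE) {
  n <- max(length(family_id), length(relative_id), length(relation),
           length(diagnosis), length(age_at_diagnosis))
  if (length(family_id) == 0) n <- 0
  df <- data.frame(family_id = rep_len(as.character(family_id), n),
                   relative_id = rep_len(as.character(relative_id), n),
                   relation = rep_len(canonical_relation(relation), n),
                   lineage = rep_len(as.character(lineage), n),
                   diagnosis = rep_len(as.character(diagnosis), n),
                   age_at_diagnosis = rep_len(as.numeric(age_at_diagnosis), n),
                   known_at_proband_diagnosis =
                     rep_len(as.logical(known_at_proband_diagnosis), n),
                   verification = rep_len(as.character(verification), n),
                   malignant = rep_len(as.logical(malignant), n),
                   consanguineous = rep_len(as.logical(consanguineous), n),
                   known_cps = rep_len(as.logical(known_cps), n),
                   stringsAsFactors = FALSE)
  validate_family(df)
}

validate_family <- function(df) {
  stopifnot(is.data.frame(df))
  deg <- relation_degrees()
  bad <- setdiff(unique(df$relation), names(deg))
  if (length(bad)) {
    rows <- which(df$relation %in% bad)
    stop("unknown relation term(s) in family table (row ",
         paste(rows, collapse = ", "), "): ", paste(bad, collapse = ", "))
  }
  df$degree <- relationship_degree(df$relation)
  if (any(!df$lineage %in% .lineage_levels)) {
    stop("lineage must be maternal, paternal or not_applicable")
  }
  first_sib <- df$relation == "sibling"
  if (any(df$degree > 1 & !first_sib & df$lineage == "not_applicable" &
            !df$relation %in% c("half_sibling"))) {
    stop("lineage may be not_applicable only for first-degree relations ",
         "and (half-)siblings")
  }
  has_ev <- !is.na(df$diagnosis)
  if (any(df$age_at_diagnosis[has_ev] < 0, na.rm = TRUE)) {
    stop("relative age_at_diagnosis must be >= 0")
  }
  if (any(!df$verification[has_ev] %in% .verification_levels)) {
    stop("verification outside vocabulary")
  }
  df
}

#' Construct an annotated variant table
#'
#' One row per germline call per patient, carrying quality-control fields,
#' functional annotation and the curated ACMG class. Missing annotation is
#' an explicit `NA`, never a silent default. Chromosomal-event records
#' (trisomy 21 carried as symbolic calls) set `event`.
#'
#' @param patient_id,chrom,pos,ref,alt Call identity (`pos` is 1-based).
#' @param genotype `"het"` or `"hom_alt"`.
#' @param depth,gq,vaf Read depth, genotype quality, variant allele fraction.
#' @param gene Gene symbol (NA if intergenic).
#' @param consequence Sequence Ontology term.
#' @param gnomad_max_af Maximum allele frequency over large gnomAD
#'   populations (NA = never observed).
#' @param cadd_phred CADD-PHRED deleteriousness score.
#' @param splice_deltas Comma-joined fractional score changes of the splice
#'   prediction programs (negative = reduction).
#' @param cryptic_site_generated Whether a strong cryptic splice site is
#'   generated.
#' @param acmg_class Curated class 1-5, NA for unassigned.
#' @param inheritance `"maternal"`, `"paternal"`, `"de_novo"` or
#'   `"unknown"`.
#' @param event Chromosomal event tag (`"trisomy_21"`, ...) or NA for
#'   sequence variants.
#' @return A validated `data.frame` with a `variant_key` column.
#' @export
variant_table <- function(patient_id, chrom, pos, ref, alt,
                          genotype = "het", depth = NA_real_, gq = NA_real_,
                          vaf = NA_real_, gene = NA_character_,
                          consequence = NA_character_,
                          gnomad_max_af = NA_real_, cadd_phred = NA_real_,
                          splice_deltas = "", cryptic_site_generated = FALSE,
                          acmg_class = NA_integer_, inheritance = "unknown",
                          event = NA_character_) {
  df <- data.frame(patient_id = as.character(patient_id),
                   chrom = as.character(chrom),
                   pos = as.integer(pos),
                   ref = as.character(ref),
                   alt = as.character(alt),
                   genotype = as.character(genotype),
                   depth = as.numeric(depth),
                   gq = as.numeric(gq),
                   vaf = as.numeric(vaf),
                   gene = as.character(gene),
                   consequence = as.character(consequence),
                   gnomad_max_af = as.numeric(gnomad_max_af),
                   cadd_phred = as.numeric(cadd_phred),
                   splice_deltas = as.character(splice_deltas),
                   cryptic_site_generated = as.logical(cryptic_site_generated),
                   acmg_class = as.integer(acmg_class),
                   inheritance = as.character(inheritance),
                   event = as.character(event),
                   stringsAsFactors = FALSE)
  validate_variants(df)
}

validate_variants <- function(df) {
  stopifnot(is.data.frame(df))
  if (any(df$pos < 1, na.rm = TRUE)) stop("pos must be >= 1 (1-based)")
  if (any(df$vaf < 0 | df$vaf > 1, na.rm = TRUE)) stop("vaf must lie in [0, 1]")
  if (any(df$gnomad_max_af < 0 | df$gnomad_max_af > 1, na.rm = TRUE)) {
    stop("gnomad_max_af must lie in [0, 1]")
  }
  if (any(!df$genotype %in% c("het", "hom_alt"))) {
    stop("genotype must be het or hom_alt")
  }
  if (any(!is.na(df$acmg_class) & !df$acmg_class %in% 1:5)) {
    stop("acmg_class must be 1-5 or NA (unassigned)")
  }
  if (any(!df$inheritance %in% c("maternal", "paternal", "de_novo", "unknown"))) {
    stop("inheritance outside vocabulary")
  }
  df$variant_key <- variant_key(df)
  df
}

#' Variant key (chrom:pos:ref:alt)
#'
#' @param df A variant table (or any data.frame with chrom/pos/ref/alt).
#' @return Character vector of keys.
#' @export
variant_key <- function(df) {
  paste(df$chrom, df$pos, df$ref, df$alt, sep = ":")
}

#' Construct a gene panel table
#'
#' @param symbol Gene symbols (unique).
#' @param in_cancer314 Membership in the 314-gene cancer panel.
#' @param in_acmg59 Membership in the 59-gene ACMG actionable list.
#' @param inheritance_mode `"monoallelic"`, `"biallelic"` or `"both"`.
#' @param onset_default `"childhood"` or `"adult"` syndrome onset.
#' @param high_population_frequency Whether the gene uses the alternate
#'   population-frequency threshold.
#' @param actionable Whether findings are disclosed as actionable.
#' @return Validated `data.frame`.
#' @export
panel_table <- function(symbol, in_cancer314, in_acmg59,
                        inheritance_mode = "monoallelic",
                        onset_default = "childhood",
                        high_population_frequency = FALSE,
                        actionable = in_acmg59) {
  df <- data.frame(symbol = as.character(symbol),
                   in_cancer314 = as.logical(in_cancer314),
                   in_acmg59 = as.logical(in_acmg59),
                   inheritance_mode = as.character(inheritance_mode),
                   onset_default = as.character(onset_default),
                   high_population_frequency = as.logical(high_population_frequency),
                   actionable = as.logical(actionable),
                   stringsAsFactors = FALSE)
  validate_panel(df)
}

validate_panel <- function(df) {
  stopifnot(is.data.frame(df))
  if (anyDuplicated(df$symbol)) {
    stop("duplicate gene symbol(s) in panel: ",
         paste(unique(df$symbol[duplicated(df$symbol)]), collapse = ", "))
  }
  if (any(!(df$in_cancer314 | df$in_acmg59))) {
    stop("every panel gene must be in the cancer-314 or the ACMG-59 list")
  }
  if (any(!df$inheritance_mode %in% c("monoallelic", "biallelic", "both"))) {
    stop("inheritance_mode outside vocabulary")
  }
  if (any(!df$onset_default %in% c("childhood", "adult"))) {
    stop("onset_default must be childhood or adult")
  }
  df
}

#' Construct a curation table
#'
#' Variant-level expert overrides: the curated ACMG class always wins over
#' the class carried in the VCF, and `onset_override` replaces the gene's
#' default onset for that specific variant (e.g. variants in APC and ATM
#' associated only with adult-onset disease).
#'
#' @param variant_key `chrom:pos:ref:alt` keys.
#' @param acmg_class Curated class (1-5, NA to keep the VCF class).
#' @param onset_override `"childhood"`, `"adult"` or `"none"`.
#' @return Validated `data.frame`.
#' @export
curation_table <- function(variant_key = character(0),
                           acmg_class = integer(0),
                           onset_override = character(0)) {
  df <- data.frame(variant_key = as.character(variant_key),
                   acmg_class = as.integer(acmg_class),
                   onset_override = as.character(onset_override),
                   stringsAsFactors = FALSE)
  if (any(!is.na(df$acmg_class) & !df$acmg_class %in% 1:5)) {
    stop("curated acmg_class must be 1-5")
  }
  if (nrow(df) && any(!df$onset_override %in% c("childhood", "adult", "none"))) {
    stop("onset_override must be childhood, adult or none")
  }
  df
}
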