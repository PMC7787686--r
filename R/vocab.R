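# Controlled vocabularies shared across the pipeline.

#' Relation vocabulary and relationship degrees
#'
#' The pedigree model uses a closed relation vocabulary covering three
#' generations around the proband. First-degree relatives are parents and
#' siblings; second-degree relatives are grandparents and parents' siblings
#' (half-siblings are treated as second degree); third-degree relatives are
#' cousins, great-grandparents and grandparents' siblings.
#'
#' @return Named integer vector mapping each relation term to its degree.
#' @export
#' @examples
#' relation_degrees()[["grandparent"]]
relation_degrees <- function() {
  c(mother = 1L, father = 1L, sibling = 1L,
    half_sibling = 2L, grandparent = 2L, parent_sibling = 2L,
    cousin = 3L, great_grandparent = 3L, grandparent_sibling = 3L)
}

#' Degree of relationship for a relation term
#'
#' @param relation Character vector of relation terms from the pedigree
#'   vocabulary (see [relation_degrees()]).
#' @return Integer vector of degrees (1, 2 or 3).
#' @export
#' @examples
#' relationship_degree(c("sibling", "grandparent", "cousin"))
relationship_degree <- function(relation) {
  deg <- relation_degrees()
  bad <- setdiff(unique(relation), names(deg))
  if (length(bad) > 0) {
    stop("unknown relation term(s): ", paste(bad, collapse = ", "))
  }
  unname(deg[relation])
}

# Synonyms accepted by the family-table reader and mapped onto the canonical
# relation vocabulary (lineage is carried separately).
.relation_synonyms <- c(
  grandfather = "grandparent", grandmother = "grandparent",
  aunt = "parent_sibling", uncle = "parent_sibling",
  great_grandfather = "great_grandparent",
  great_grandmother = "great_grandparent",
  brother = "sibling", sister = "sibling",
  half_brother = "half_sibling", half_sister = "half_sibling"
)

canonical_relation <- function(relation) {
  rel <- tolower(trimws(relation))
  syn <- unname(.relation_synonyms[rel])
  unname(ifelse(is.na(syn), rel, syn))
}

.sex_levels <- c("male", "female")
.lineage_levels <- c("maternal", "paternal", "not_applicable")
.verification_levels <- c("verified", "declined_consent", "unverifiable",
                          "abroad", "reported_only")
.tier_levels <- c("confirmed_childhood", "confirmed_adult", "biallelic_carrier",
                  "criteria_only", "family_history_only", "none")
.organ_levels <- c("hematologic", "CNS", "solid_defined", "breast",
                   "gastrointestinal", "other")
.chromosomal_events <- c("trisomy_21", "upd_11p", "klinefelter", "other")
.tumor_flag_levels <- c("multiple_primaries", "bilateral_or_multifocal",
                        "tumor_analysis_suggests_germline",
                        "neoplasm_in_jongmans_c2_list",
                        "neoplasm_in_mipogg_direct_list")
.phenotype_flag_levels <- c("congenital_anomalies", "developmental_delay",
                            "growth_anomalies", "skin_aberrations",
                            "immune_deficiency", "dysmorphic_cancer_related")

#' Neoplasms indicating an underlying CPS (Jongmans' criterion 2)
#'
#' Tumor types for which the diagnosis itself raises the suspicion of a
#' predisposition syndrome. The packaged list covers the published examples
#' and can be extended via the `extra` argument of [evaluate_jongmans()].
#'
#' @return Character vector of normalized diagnosis terms.
#' @export
jongmans_indicative_neoplasms <- function() {
  c("hypodiploid all",
    "botryoid rhabdomyosarcoma",
    "gastrointestinal stromal tumor",
    "retinoblastoma",
    "schwannoma",
    "subependymal giant cell astrocytoma")
}

#' Tumors warranting direct genetics referral under MIPOGG
#'
#' @return Character vector of normalized diagnosis terms.
#' @export
mipogg_direct_referral_tumors <- function() {
  c(# CNS and ocular
    "atypical teratoid rhabdoid tumor", "choroid plexus carcinoma",
    "dysplastic cerebellar gangliocytoma", "endolymphatic sac tumor",
    "hemangioblastoma", "optic pathway glioma", "pineoblastoma",
    "pituitary adenoma", "retinoblastoma",
    "subependymal giant cell astrocytoma", "vestibular schwannoma",
    # renal and neuroblastic
    "cystic nephroma", "renal angiomyolipoma", "renal cell carcinoma",
    "renal rhabdoid tumor",
    # bone and soft tissue
    "desmoid tumor", "extrarenal rhabdoid tumor", "gardner fibroma",
    "malignant peripheral nerve sheath tumor",
    "nasal chondromesenchymal hamartoma",
    # other
    "adrenocortical carcinoma", "cardiac rhabdomyoma",
    "colorectal carcinoma", "gastrointestinal stromal tumor",
    "hepatoblastoma", "medullary thyroid cancer",
    "ovarian sertoli-leydig cell tumor", "parathyroid tumor",
    "pheochromocytoma", "paraganglioma", "pleuropulmonary blastoma",
    "trichilemmoma", "small cell carcinoma of the ovary of hypercalcemic type",
    "carcinoma of the breast", "carcinoma of the lung",
    "carcinoma of the cervix", "carcinoma of the uterus",
    "carcinoma of the bladder")
}

normalize_diagnosis <- function(x) {
  x <- tolower(trimws(x))
  # common shorthand used in clinical tables
  map <- c("at/rt" = "atypical teratoid rhabdoid tumor",
           "atrt" = "atypical teratoid rhabdoid tumor",
           "sega" = "subependymal giant cell astrocytoma",
           "optic nerve glioma" = "optic pathway glioma",
           "mpnst" = "malignant peripheral nerve sheath tumor",
           "sccoht" = "small cell carcinoma of the ovary of hypercalcemic type",
           "small cell carcinoma of the ovary" =
             "small cell carcinoma of the ovary of hypercalcemic type")
  hit <- map[x]
  ifelse(is.na(hit), x, hit)
}

#' Diagnosis group of a pediatric cancer diagnosis
#'
#' Maps free-text diagnoses onto the three cohort-level groups used for
#' patient stratification: hematologic malignancies, tumors of the central
#' nervous system, and solid tumors. The mapping is total: any term not
#' recognized as hematologic or CNS is a solid tumor.
#'
#' @param diagnosis Character vector of diagnoses.
#' @return Character vector with values `"hematologic"`, `"CNS"` or
#'   `"solid"`.
#' @export
#' @examples
#' diagnosis_group(c("precursor B-ALL", "medulloblastoma", "Wilms tumor"))
diagnosis_group <- function(diagnosis) {
  d <- normalize_diagnosis(diagnosis)
  hema <- grepl("leukemia|leukaemia|lymphoma|myelodysplastic|myeloid|histiocytosis|\\ball\\b|-all\\b",
                d)
  cns <- grepl("glioma|glioblastoma|astrocytoma|ependymoma|medulloblastoma|schwannoma|craniopharyngioma|ganglioglioma|pineoblastoma|choroid plexus|gangliocytoma|\\bcns\\b|brain",
               d)
  out <- rep("solid", length(d))
  out[cns] <- "CNS"
  out[hema] <- "hematologic"
  out
}

#' Organ group of a cancer diagnosis
#'
#' Classifies a (proband or relative) cancer diagnosis into the organ groups
#' used for family-history concordance: hematologic, CNS, defined solid
#' tumors (any kidney tumor, retinoblastoma, bone tumors, neuroendocrine
#' tumors, gastrointestinal stromal tumors, rhabdomyosarcoma), breast,
#' gastrointestinal, or other. Unknown terms map to `"other"`.
#'
#' @param diagnosis Character vector of diagnoses.
#' @return Character vector of organ groups.
#' @export
#' @examples
#' organ_group(c("Wilms tumor", "medulloblastoma", "melanoma"))
organ_group <- function(diagnosis) {
  d <- normalize_diagnosis(diagnosis)
  out <- rep("other", length(d))
  gi <- grepl("colon|colorectal|gastric|stomach|esophag|oesophag|pancrea|cholangio|hepat|liver|bowel|rectal|intestin|gastrointestinal",
              d)
  solid <- grepl("kidney|wilms|renal|retinoblastoma|\\bbone\\b|osteosarcoma|ewing|neuroendocrine|pheochromocytoma|paraganglioma|carcinoid|gastrointestinal stromal|\\bgist\\b|rhabdomyosarcoma|medullary thyroid",
                 d)
  breast <- grepl("breast", d)
  cns <- grepl("glioma|glioblastoma|astrocytoma|ependymoma|medulloblastoma|schwannoma|craniopharyngioma|ganglioglioma|pineoblastoma|choroid plexus|gangliocytoma|\\bcns\\b|brain",
               d)
  hema <- grepl("leukemia|leukaemia|lymphoma|myelodysplastic|myeloid|myelofibrosis|histiocytosis|\\ball\\b|-all\\b",
                d)
  out[gi] <- "gastrointestinal"
  out[solid] <- "solid_defined"
  out[breast] <- "breast"
  out[cns] <- "CNS"
  out[hema] <- "hematologic"
  out
}

# Flag-set helpers: sets are carried as comma-joined strings in table cells so
# that every container round-trips through TSV unchanged.
flags_to_string <- function(x) {
  vapply(x, function(f) paste(sort(unique(f)), collapse = ","), character(1))
}

string_to_flags <- function(x) {
  lapply(x, function(s) {
    if (is.na(s) || !nzchar(s)) character(0) else strsplit(s, ",", fixed = TRUE)[[1]]
  })
}

#' Test whether a flag set contains a flag
#'
#' @param x Character vector of comma-joined flag sets.
#' @param flag Single flag to look for.
#' @return Logical vector.
#' @export
has_flag <- function(x, flag) {
  vapply(string_to_flags(x), function(f) flag %in% f, logical(1))
}
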