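# The encoded study cohort: a nationwide series of 198 consecutive
# pediatric cancer patients, reconstructed from the published per-patient
# tables. Patients whose findings are printed are encoded in detail
# (variants, pedigrees, phenotypes); the remainder of the cohort is filled
# with patients carrying exactly the published marginal properties
# (diagnosis-group mix, criteria fulfillment counts, feedback levels).
# Where a patient's printed criteria outcome cannot be derived from printed
# inputs, the outcome is stored as a recorded value (see
# [criteria_outcomes()]).

.pkg_cache <- new.env(parent = emptyenv())

extdata <- function(name) {
  path <- system.file("extdata", name, package = "cpsscreen")
  if (!nzchar(path)) stop("packaged fixture not found: ", name)
  path
}

#' The packaged gene panel
#'
#' A synthetic stand-in for the study's screening panel with the published
#' cardinality (314 cancer genes, 59 ACMG actionable genes) and correct
#' attributes for every gene named in the published findings tables;
#' remaining slots are filled with placeholder symbols.
#'
#' @return A panel table.
#' @export
default_panel <- function() {
  if (is.null(.pkg_cache$panel)) {
    .pkg_cache$panel <- read_gene_panel(extdata("panel_synthetic.tsv"))
  }
  .pkg_cache$panel
}

# detailed probands: id, sex, age, diagnosis, tumor flags, phenotype flags,
# chromosomal events
.study_detailed_probands <- function() {
  p <- function(id, sex, age, dx, tf = "", pf = "", ce = "") {
    data.frame(patient_id = id, sex = sex, age = age, dx = dx, tf = tf,
               pf = pf, ce = ce, stringsAsFactors = FALSE)
  }
  cafe <- "dysmorphic_cancer_related,skin_aberrations"
  down <- "developmental_delay,dysmorphic_cancer_related"
  rows <- rbind(
    # childhood-onset CPS patients
    p("A1", "male", 4, "precursor B-ALL"),
    p("A2", "female", 14, "osteosarcoma"),
    p("B1", "male", 9, "acute promyelocytic leukemia"),
    p("C1", "female", 3, "acute myeloid leukemia"),
    p("E1", "male", 5, "acute myeloid leukemia", pf = cafe),
    p("E2", "male", 15, "malignant peripheral nerve sheath tumor", pf = cafe),
    p("E3", "female", 7, "optic nerve glioma", pf = cafe),
    p("E4", "male", 6, "pilocytic astrocytoma", pf = cafe),
    p("F1", "male", 12, "osteosarcoma"),
    p("G1", "male", 10, "plasmacytoid dendritic cell leukemia", pf = down),
    p("H1", "male", 0, "retinoblastoma"),
    p("H2", "male", 1, "retinoblastoma"),
    p("H3", "female", 0, "retinoblastoma"),
    p("H4", "male", 2, "retinoblastoma"),
    p("I1", "male", 1, "Wilms tumor",
      pf = "dysmorphic_cancer_related,growth_anomalies", ce = "upd_11p"),
    p("J1", "female", 8, "subependymal giant cell astrocytoma",
      pf = "developmental_delay,skin_aberrations"),
    p("K1", "female", 16, "synovial sarcoma"),
    p("L1", "male", 1, "acute megakaryoblastic leukemia", pf = down,
      ce = "trisomy_21"),
    p("L2", "male", 1, "acute megakaryoblastic leukemia", pf = down,
      ce = "trisomy_21"),
    p("L3", "female", 13, "Hodgkin lymphoma", pf = down, ce = "trisomy_21"),
    p("L4", "female", 4, "precursor B-ALL", pf = down, ce = "trisomy_21"),
    # adult-onset CPS patients
    p("M1", "male", 6, "precursor B-ALL"),
    p("N1", "male", 11, "precursor T-ALL"),
    p("N2", "female", 2, "Langerhans cell histiocytosis"),
    p("O1", "male", 13, "precursor T-ALL"),
    p("Q1", "male", 0, "neuroblastoma", pf = "developmental_delay"),
    p("Q2", "female", 3, "Wilms tumor"),
    p("R1", "male", 5, "rhabdomyosarcoma"),
    p("S1", "male", 2, "Wilms tumor"),
    # heterozygous carriers of biallelic-CPS-gene PVs
    p("U01", "male", 7, "acute myeloid leukemia"),
    p("U02", "female", 3, "precursor B-ALL"),
    p("U03", "male", 12, "chronic myeloid leukemia"),
    p("U04", "male", 4, "rhabdomyosarcoma"),
    p("U05", "male", 9, "precursor T-ALL",
      pf = "congenital_anomalies,dysmorphic_cancer_related"),
    p("U06", "female", 10, "astrocytoma"),
    p("U07", "male", 5, "precursor B-ALL"),
    p("U08", "female", 2, "acute myeloid leukemia"),
    p("U09", "female", 1, "yolk sac tumor"),
    p("U10", "male", 6, "precursor B-ALL"),
    p("U11", "male", 14, "precursor T-ALL"),
    p("U12", "female", 4, "precursor B-ALL"),
    p("U13", "male", 11, "lymphoma"),
    p("U14", "female", 3, "rhabdomyosarcoma"),
    p("U15", "male", 2, "Wilms tumor"),
    p("U16", "female", 5, "precursor B-ALL"),
    p("U17", "male", 9, "ganglioglioma"),
    p("U18", "female", 7, "craniopharyngioma"),
    p("U19", "male", 3, "precursor B-ALL"),
    p("U20", "female", 12, "lymphoma"),
    p("U21", "male", 8, "glioma"),
    p("U22", "female", 6, "craniopharyngioma"),
    p("U23", "male", 4, "precursor B-ALL"),
    # ACMG actionable secondary findings outside CPS genes
    p("V01", "male", 9, "Burkitt lymphoma"),
    p("V02", "female", 11, "glioma"),
    p("V03", "male", 6, "diffuse intrinsic pontine glioma"),
    p("V04", "female", 4, "precursor B-ALL"),
    p("V05", "male", 13, "glioblastoma"),
    p("V06", "female", 8, "anaplastic large-cell lymphoma"))
  rows
}

.study_filler_probands <- function() {
  # 140 filler patients reproducing the published marginals:
  # 42 fulfill clinical criteria without a PV (28 both rule sets,
  # 4 Jongmans only, 10 MIPOGG only), 98 fulfill neither.
  hema <- c("precursor B-ALL", "lymphoma", "acute myeloid leukemia",
            "precursor T-ALL", "Langerhans cell histiocytosis",
            "myelodysplastic syndrome")
  cns <- c("low-grade glioma", "high-grade glioma", "ependymoma",
           "medulloblastoma")
  solid <- c("Wilms tumor", "neuroblastoma", "Ewing's sarcoma",
             "osteosarcoma", "rhabdomyosarcoma")
  grp <- rep(c("h", "c", "s"), c(75, 33, 32))
  dx <- character(140)
  dx[grp == "h"] <- rep_len(hema, 75)
  dx[grp == "c"] <- rep_len(cns, 33)
  dx[grp == "s"] <- rep_len(solid, 32)
  id <- sprintf("F%03d", seq_len(140))
  sex <- rep_len(c("male", "male", "female", "male", "female"), 140)
  age <- rep_len(c(0:17, 2, 4, 1, 3, 0, 5), 140)
  tf <- rep("", 140)
  pf <- rep("", 140)
  ce <- rep("", 140)
  role <- rep("neither", 140)
  role[1:28] <- "both"      # anamnestic: more than one primary tumor
  role[29:31] <- "j_only"   # two same-lineage relatives under 45
  role[32] <- "j_only_pheno"
  role[33:42] <- "m_only"   # a parent with cancer before 50
  tf[role == "both"] <- "multiple_primaries"
  pf[role == "j_only_pheno"] <- "developmental_delay"
  ce[role == "j_only_pheno"] <- "klinefelter"
  fb <- rep(3L, 140)
  fb[43:61] <- 1L
  fb[62:85] <- 2L
  list(probands = data.frame(patient_id = id, sex = sex, age = age,
                             dx = dx, tf = tf, pf = pf, ce = ce,
                             fb = fb, stringsAsFactors = FALSE),
       role = role)
}

.study_filler_families <- function(filler) {
  role <- filler$role
  id <- filler$probands$patient_id
  rows <- list()
  for (i in which(role == "j_only")) {
    rows[[length(rows) + 1]] <- family_table(
      id[i], paste0(id[i], c("_ps1", "_ps2")), "parent_sibling", "maternal",
      diagnosis = c("breast cancer", "ovarian cancer"),
      age_at_diagnosis = c(40, 43), verification = "verified")
  }
  for (i in which(role == "m_only")) {
    rows[[length(rows) + 1]] <- family_table(
      id[i], paste0(id[i], "_fa"), "father", "not_applicable",
      diagnosis = "colon cancer", age_at_diagnosis = 47,
      verification = "verified")
  }
  do.call(rbind, rows)
}

# criteria outcomes printed without derivable inputs: stored as recorded
.study_recorded_outcomes <- function() {
  data.frame(
    patient_id = c("B1", "F1", "Q2", "U06", "U08", "U22", "U17",
                   "U02", "U13", "U15"),
    jongmans = c(TRUE, TRUE, TRUE, TRUE, TRUE, TRUE, TRUE,
                 FALSE, FALSE, FALSE),
    mipogg = c(TRUE, TRUE, TRUE, TRUE, TRUE, TRUE, FALSE,
               TRUE, TRUE, TRUE),
    stringsAsFactors = FALSE)
}

#' The encoded study cohort
#'
#' Reconstructs the full 198-patient cohort from the published per-patient
#' tables: 21 childhood-onset CPS patients (including four with trisomy 21
#' and one with paternal UPD 11p), 9 carriers of adult-onset CPS PVs (one
#' of whom also carries a childhood-onset deletion and is counted in the
#' childhood tier), 23 additional heterozygous carriers of
#' biallelic-CPS-gene PVs, six patients with ACMG actionable secondary
#' findings outside CPS genes, and 140 filler patients reproducing the
#' published criteria-fulfillment and feedback-level marginals.
#'
#' @return A `cps_cohort` bundle (probands, relatives, variants, curation,
#'   recorded criteria outcomes, manifest).
#' @export
study_cohort <- function() {
  det <- .study_detailed_probands()
  fil <- .study_filler_probands()
  probands <- proband_table(
    patient_id = c(det$patient_id, fil$probands$patient_id),
    sex = c(det$sex, fil$probands$sex),
    age_at_diagnosis = c(det$age, fil$probands$age),
    diagnosis = c(det$dx, fil$probands$dx),
    tumor_flags = c(det$tf, fil$probands$tf),
    phenotype_flags = c(det$pf, fil$probands$pf),
    chromosomal_events = c(det$ce, fil$probands$ce),
    feedback_level = c(rep(3L, nrow(det)), fil$probands$fb))

  relatives <- rbind(read_family_table(extdata("study_families.tsv")),
                     .study_filler_families(fil))
  variants <- rbind(read_annotated_vcf(extdata("study_pvs_cps.vcf")),
                    read_annotated_vcf(extdata("study_pvs_other.vcf")))
  curation <- read_curation_table(extdata("curation.tsv"))

  structure(list(probands = probands, relatives = relatives,
                 variants = variants, curation = curation,
                 recorded_criteria = .study_recorded_outcomes(),
                 manifest = list(source = "encoded published tables")),
            class = "cps_cohort")
}

#' Run the screening pipeline on the encoded study cohort
#'
#' @return As [run_pipeline()].
#' @export
study_pipeline <- function() {
  co <- study_cohort()
  run_pipeline(co, panel = default_panel(),
               recorded = co$recorded_criteria)
}
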