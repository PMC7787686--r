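# Shared in-code fixtures for the test suite.

test_path_extdata <- function(name) {
  system.file("extdata", name, package = "cpsscreen")
}

# a minimal variant row that passes every triage filter
good_variant <- function(patient_id = "P1", gene = "TP53", pos = 1000L,
                         acmg_class = 5L, ...) {
  variant_table(patient_id = patient_id, chrom = "17", pos = pos,
                ref = "A", alt = "G", genotype = "het",
                depth = 30, gq = 99, vaf = 0.5, gene = gene,
                consequence = "missense_variant", gnomad_max_af = 0.001,
                cadd_phred = 25, acmg_class = acmg_class, ...)
}

# one decoy per failure mode, each failing exactly one triage filter
decoy_variants <- function(patient_id = "P1") {
  d <- rbind(
    good_variant(patient_id, pos = 9001L),
    good_variant(patient_id, pos = 9002L),
    good_variant(patient_id, pos = 9003L),
    good_variant(patient_id, pos = 9004L),
    good_variant(patient_id, pos = 9005L),
    good_variant(patient_id, pos = 9006L),
    good_variant(patient_id, pos = 9007L))
  d$depth[1] <- 7                        # below read-depth threshold
  d$gq[2] <- 19                          # below genotype quality
  d$vaf[3] <- 0.19                       # below allele fraction
  d$consequence[4] <- "intron_variant"
  d$consequence[5] <- "5_prime_UTR_variant"
  d$gene[6] <- "NOT_A_PANEL_GENE"
  d$gnomad_max_af[7] <- 0.02             # too common
  d$expected_reason <- c("call_quality", "call_quality", "call_quality",
                         "consequence", "consequence", "off_panel",
                         "frequency")
  d
}

# proband + empty pedigree scaffolding for criteria tests
one_proband <- function(diagnosis = "precursor B-ALL", tumor_flags = "",
                        phenotype_flags = "", id = "P1") {
  proband_table(id, "male", 5L, diagnosis, tumor_flags = tumor_flags,
                phenotype_flags = phenotype_flags)
}

empty_family <- function(family_id = "P1") {
  family_table(character(0), character(0), character(0), character(0))
}

relative_event <- function(family_id, rid, relation, lineage, dx, age,
                           known = TRUE, malignant = TRUE,
                           consang = FALSE, known_cps = FALSE) {
  family_table(family_id, rid, relation, lineage, diagnosis = dx,
               age_at_diagnosis = age, known_at_proband_diagnosis = known,
               malignant = malignant, consanguineous = consang,
               known_cps = known_cps)
}

tiny_panel <- function() {
  panel_table(symbol = c("TP53", "RB1", "FANCC", "BRCA2", "CHEK2", "KCNQ1"),
              in_cancer314 = c(TRUE, TRUE, TRUE, TRUE, TRUE, FALSE),
              in_acmg59 = c(TRUE, TRUE, FALSE, TRUE, FALSE, TRUE),
              inheritance_mode = c("monoallelic", "monoallelic", "biallelic",
                                   "monoallelic", "monoallelic",
                                   "monoallelic"),
              onset_default = c("childhood", "childhood", "childhood",
                                "adult", "adult", "adult"),
              high_population_frequency = c(FALSE, FALSE, FALSE, FALSE,
                                            TRUE, FALSE))
}
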