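# Onset, zygosity, trio inheritance and tier assignment.

test_that("trio inheritance assignment covers all printed patterns", {
  expect_equal(assign_inheritance("het", "het", "ref"), "maternal")
  expect_equal(assign_inheritance("het", "ref", "het"), "paternal")
  expect_equal(assign_inheritance("het", "ref", "ref"), "de_novo")
  expect_equal(assign_inheritance("het", "het", "het"), "unknown")
  expect_equal(assign_inheritance("het", "het", NA), "unknown")
  expect_error(assign_inheritance("ref", "het", "ref"), "does not carry")
})

test_that("inheritance assignment inverts trio generation exhaustively", {
  for (origin in c("maternal", "paternal", "de_novo")) {
    gt <- generate_trio_genotypes(origin)
    expect_equal(assign_inheritance(gt[["child"]], gt[["mother"]],
                                    gt[["father"]]), origin)
  }
})

test_that("onset uses the gene default unless a variant override exists", {
  panel <- default_panel()
  v <- rbind(good_variant(gene = "TP53", pos = 1L),
             good_variant(gene = "APC", pos = 2L),
             good_variant(gene = "BRCA2", pos = 3L))
  v <- apply_curation(v, curation_table(v$variant_key[2], NA_integer_,
                                        "adult"))
  expect_equal(assign_onset(v, panel), c("childhood", "adult", "adult"))
})

test_that("zygosity resolution distinguishes trans pairs from phase-unknown", {
  expect_equal(resolve_zygosity(c("maternal", "paternal")),
               "biallelic_confirmed_trans")
  expect_equal(resolve_zygosity("unknown"), "monoallelic")
  expect_equal(resolve_zygosity(c("unknown", "unknown")),
               "biallelic_phase_unknown")
  expect_equal(resolve_zygosity("unknown", genotypes = "hom_alt"),
               "biallelic_confirmed_trans")
})

test_that("tier assignment follows the suspicion-triangle precedence", {
  panel <- tiny_panel()
  pro <- proband_table(c("P1", "P2", "P3", "P4"), "male", 5L,
                       c("lymphoma", "lymphoma", "lymphoma", "lymphoma"))
  v <- rbind(good_variant("P1", gene = "TP53", pos = 1L),   # childhood PV
             good_variant("P1", gene = "BRCA2", pos = 2L),  # + adult PV
             good_variant("P2", gene = "FANCC", pos = 3L),  # carrier het
             good_variant("P3", gene = "BRCA2", pos = 4L))  # adult PV
  tri <- run_triage(v, panel)
  crit <- data.frame(patient_id = c("P1", "P2", "P3", "P4"),
                     jongmans_fulfilled = c(FALSE, FALSE, FALSE, TRUE),
                     mipogg_referral = FALSE)
  a <- classify_cohort(pro, tri, panel, crit)
  expect_equal(a$tier, c("confirmed_childhood", "biallelic_carrier",
                         "confirmed_adult", "criteria_only"))
  # the childhood+adult patient counts once, in the childhood tier,
  # but still belongs to the adult-PV carrier group and is multi-PV
  expect_true(a$has_adult_pv[1])
  expect_true(a$multi_pv[1])
  expect_false(a$multi_pv[2])
  # flipping lower-tier evidence never changes a confirmed assignment
  crit$jongmans_fulfilled <- TRUE
  a2 <- classify_cohort(pro, tri, panel, crit,
                        family_flags = data.frame(
                          patient_id = pro$patient_id,
                          any_family_cancer = TRUE))
  expect_equal(a2$tier[1:3], a$tier[1:3])
})

test_that("chromosomal events qualify for the childhood tier", {
  panel <- tiny_panel()
  pro <- proband_table(c("T1", "T2"), "female", 2L, "precursor B-ALL",
                       chromosomal_events = c("trisomy_21", "klinefelter"))
  tri <- run_triage(good_variant("none", pos = 99L), panel)
  a <- classify_cohort(pro, tri[0, ], panel)
  expect_equal(a$tier, c("confirmed_childhood", "none"))
})

test_that("a biallelic pair in a recessive childhood gene confirms CPS", {
  panel <- tiny_panel()
  pro <- proband_table("B1", "male", 4L, "acute myeloid leukemia")
  v <- rbind(good_variant("B1", gene = "FANCC", pos = 1L),
             good_variant("B1", gene = "FANCC", pos = 2L))
  v$inheritance <- c("maternal", "paternal")
  a <- classify_cohort(pro, run_triage(v, panel), panel)
  expect_equal(a$tier, "confirmed_childhood")
  expect_match(a$zygosity_notes, "biallelic_confirmed_trans")
  expect_false(a$phase_caveat)
  # without phase evidence the pair still confirms, with a caveat flag
  v$inheritance <- "unknown"
  a2 <- classify_cohort(pro, run_triage(v, panel), panel)
  expect_equal(a2$tier, "confirmed_childhood")
  expect_true(a2$phase_caveat)
})

test_that("the encoded cohort reproduces the published patient counts", {
  pp <- study_pipeline()
  a <- pp$assignments
  expect_equal(sum(a$tier == "confirmed_childhood"), 21L)
  expect_equal(sum(a$tier == "confirmed_adult"), 8L)
  expect_equal(sum(a$has_adult_pv), 9L)
  expect_equal(sum(a$tier %in% c("confirmed_childhood", "confirmed_adult")),
               29L)
  expect_equal(sum(a$tier == "biallelic_carrier"), 23L)
  expect_equal(sum(a$has_biallelic_gene_pv), 27L)
  multi <- detect_multi_pv(a)
  expect_equal(multi$patient_id,
               c("E2", "E3", "G1", "L4", "N2", "S1", "U01"))
  # the biallelic DDX41 + NBN patient carries three findings
  expect_equal(multi$n_findings[multi$patient_id == "G1"], 3L)
  # tier partition
  expect_equal(sum(pp$summary$tier_counts), 198L)
})
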