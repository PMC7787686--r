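# Domain types and interchange formats.

test_that("annotated VCF round-trips and preserves missing annotation", {
  v <- rbind(good_variant("P1", pos = 100L),
             good_variant("P2", gene = "RB1", pos = 200L, acmg_class = 3L),
             good_variant("P3", pos = 300L))
  v$cadd_phred[3] <- NA          # record without a CADD annotation
  v$gnomad_max_af[2] <- NA
  v$splice_deltas[1] <- "-0.12,-0.15,-0.11,-0.02"
  v$inheritance <- c("maternal", "de_novo", "unknown")
  path <- withr::local_tempfile(fileext = ".vcf")
  write_annotated_vcf(v, path)
  back <- read_annotated_vcf(path)
  expect_equal(back[names(v)], v, ignore_attr = TRUE)
  expect_true(is.na(back$cadd_phred[3]))
  expect_true(is.na(back$gnomad_max_af[2]))
})

test_that("the encoded RB1 nonsense variant parses with its curated class", {
  v <- read_annotated_vcf(test_path_extdata("study_pvs_cps.vcf"))
  rb1 <- v[v$gene %in% "RB1" & v$consequence == "stop_gained", ]
  expect_equal(nrow(rb1), 1L)
  expect_equal(rb1$acmg_class, 5L)
  expect_equal(rb1$patient_id, "H1")
})

test_that("unknown consequence terms warn but are retained", {
  v <- good_variant()
  v$consequence <- "mystery_term"
  path <- withr::local_tempfile(fileext = ".vcf")
  write_annotated_vcf(v, path)
  expect_warning(back <- read_annotated_vcf(path), "mystery_term")
  expect_equal(back$consequence, "mystery_term")
})

test_that("family table round-trips, maps synonyms and rejects bad terms", {
  fam <- relative_event("FAM1", "gf", "grandfather", "maternal",
                        "chronic lymphoblastic leukemia", 62)
  path <- withr::local_tempfile(fileext = ".tsv")
  write_family_table(fam, path)
  back <- read_family_table(path)
  expect_equal(back$relation, "grandparent")
  expect_equal(back$lineage, "maternal")
  expect_equal(back$age_at_diagnosis, 62)
  expect_equal(organ_group(back$diagnosis), "hematologic")
  # round trip on canonical rows
  write_family_table(back, path)
  expect_equal(read_family_table(path), back, ignore_attr = TRUE)

  bad <- fam
  bad$relation <- "stepcousin"
  write.table(bad[setdiff(names(bad), "degree")], path, sep = "\t",
              quote = FALSE, row.names = FALSE)
  expect_error(read_family_table(path), "stepcousin")
})

test_that("a family with zero relatives is valid", {
  fam <- empty_family()
  expect_s3_class(fam, "data.frame")
  expect_equal(nrow(fam), 0L)
  out <- criteria_outcomes(one_proband(), fam)
  expect_false(out$jongmans_fulfilled)
})

test_that("packaged panel has the published cardinality", {
  panel <- default_panel()
  expect_equal(sum(panel$in_cancer314), 314L)
  expect_equal(sum(panel$in_acmg59), 59L)
  # genes in both lists are counted once
  expect_equal(nrow(panel), length(unique(panel$symbol)))
  both <- panel$in_cancer314 & panel$in_acmg59
  expect_gt(sum(both), 0)
  expect_lt(nrow(panel), 314 + 59)
})

test_that("panel round-trips and rejects duplicate symbols", {
  panel <- tiny_panel()
  path <- withr::local_tempfile(fileext = ".tsv")
  write_gene_panel(panel, path)
  expect_equal(read_gene_panel(path), panel, ignore_attr = TRUE)
  expect_error(panel_table(c("TP53", "TP53"), TRUE, TRUE), "duplicate")
})

test_that("proband and curation tables round-trip", {
  pro <- proband_table(c("P1", "P2"), c("male", "female"), c(3L, 16L),
                       c("retinoblastoma", "medulloblastoma"),
                       tumor_flags = c("multiple_primaries", ""),
                       chromosomal_events = c("", "trisomy_21"),
                       feedback_level = c(1L, 3L))
  expect_equal(pro$diagnosis_group, c("solid", "CNS"))
  path <- withr::local_tempfile(fileext = ".tsv")
  write_proband_table(pro, path)
  expect_equal(read_proband_table(path), pro, ignore_attr = TRUE)

  cur <- curation_table("5:112175211:T:A", 4L, "adult")
  write_curation_table(cur, path)
  expect_equal(read_curation_table(path), cur, ignore_attr = TRUE)
})

test_that("triage config round-trips through YAML and validates", {
  cfg <- triage_config(max_af_high_freq_genes = 0.04)
  path <- withr::local_tempfile(fileext = ".yaml")
  write_triage_config(cfg, path)
  expect_equal(read_triage_config(path), cfg)
  expect_error(triage_config(min_depth = 0), "strictly positive")
  expect_error(triage_config(max_af_high_freq_genes = 0.001), ">= max_af")
})

test_that("every relation term maps to exactly one degree, no fall-through", {
  vocab <- names(relation_degrees())
  deg <- relationship_degree(vocab)
  expect_true(all(deg %in% 1:3))
  expect_length(deg, length(vocab))
  expect_equal(relationship_degree(c("grandparent", "cousin", "sibling",
                                     "half_sibling")),
               c(2L, 3L, 1L, 2L))
  expect_error(relationship_degree("neighbor"), "unknown relation")
})

test_that("proband invariants are enforced", {
  expect_error(proband_table("P1", "male", 18L, "lymphoma"), "\\[0, 17\\]")
  expect_error(proband_table("P1", "male", 3L, "lymphoma",
                             feedback_level = 4L), "feedback_level")
  expect_error(proband_table("P1", "other", 3L, "lymphoma"), "sex")
})
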