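# Jongmans' and MIPOGG rule engines, degrees, concordance, verification.

test_that("published example patients evaluate correctly", {
  # an indicative neoplasm alone fulfills Jongmans (criterion 2)
  j <- evaluate_jongmans(one_proband("retinoblastoma"), empty_family())
  expect_true(j$c2_indicative_neoplasm)
  expect_true(j$jongmans_fulfilled)

  # a first-degree relative with cancer before 45, known at diagnosis
  fam <- relative_event("P1", "mo", "mother", "not_applicable",
                        "breast cancer", 40)
  j <- evaluate_jongmans(one_proband(), fam)
  expect_true(j$c1_first_degree_under45)

  # the same event not known at the proband's diagnosis does not count
  fam2 <- relative_event("P1", "fa", "father", "not_applicable",
                         "pheochromocytoma", 34, known = FALSE)
  j2 <- evaluate_jongmans(one_proband(), fam2)
  expect_false(j2$jongmans_fulfilled)
  m2 <- evaluate_mipogg(one_proband(), fam2)
  expect_false(m2$mipogg_referral)

  # MIPOGG: direct-referral tumor
  m <- evaluate_mipogg(one_proband("retinoblastoma"), empty_family())
  expect_true(m$direct_referral_tumor)

  # MIPOGG: a parent with cancer before 50
  m <- evaluate_mipogg(one_proband(),
                       relative_event("P1", "fa", "father",
                                      "not_applicable", "colon cancer", 49))
  expect_true(m$family_close_under18_or_parent_sib_under50)

  # MIPOGG: close relative with a cancer of the same organ system
  m <- evaluate_mipogg(one_proband("acute myeloid leukemia"),
                       relative_event("P1", "gf", "grandfather", "maternal",
                                      "chronic lymphoblastic leukemia", 62))
  expect_true(m$family_same_type_or_organ)
  expect_true(m$mipogg_referral)
})

test_that("same-lineage counting pools first and second degree, never sides", {
  fam <- rbind(
    relative_event("P1", "aunt_m", "aunt", "maternal", "breast cancer", 40),
    relative_event("P1", "gm_p", "grandmother", "paternal",
                   "ovarian cancer", 43))
  j <- evaluate_jongmans(one_proband(), fam)
  expect_false(j$c1_two_relatives_same_lineage_under45)
  fam2 <- rbind(fam,
                relative_event("P1", "gf_m", "grandfather", "maternal",
                               "lung cancer", 44))
  j2 <- evaluate_jongmans(one_proband(), fam2)
  expect_true(j2$c1_two_relatives_same_lineage_under45)
})

test_that("benign tumors never count toward the criteria", {
  fam <- relative_event("P1", "uncle", "uncle", "maternal",
                        "tumor on heart valve", 0, malignant = FALSE)
  expect_false(evaluate_mipogg(one_proband(), fam)$mipogg_referral)
  expect_false(evaluate_jongmans(one_proband(), fam)$jongmans_fulfilled)
})

test_that("organ grouping matches the published definitions", {
  expect_equal(organ_group(c("Wilms tumor", "medulloblastoma", "melanoma")),
               c("solid_defined", "CNS", "other"))
  expect_equal(organ_group("gastrointestinal stromal tumor"), "solid_defined")
  expect_equal(organ_group("esophageal cancer"), "gastrointestinal")
  expect_equal(organ_group("breast cancer"), "breast")
})

test_that("criteria outcomes are order-independent and monotone", {
  fam <- rbind(
    relative_event("P1", "mo", "mother", "not_applicable", "breast cancer", 40),
    relative_event("P1", "gf", "grandfather", "paternal", "lung cancer", 70),
    relative_event("P1", "aunt", "aunt", "maternal", "melanoma", 30))
  p <- one_proband()
  base_j <- evaluate_jongmans(p, fam)
  base_m <- evaluate_mipogg(p, fam)
  set.seed(7)
  for (i in 1:5) {
    perm <- fam[sample(nrow(fam)), ]
    expect_equal(evaluate_jongmans(p, perm), base_j)
    expect_equal(evaluate_mipogg(p, perm), base_m)
  }
  # adding a qualifying event never turns a fulfilled criterion false
  more <- rbind(fam, relative_event("P1", "sib", "sibling",
                                    "not_applicable", "lymphoma", 10))
  j2 <- evaluate_jongmans(p, more)
  comp <- setdiff(names(base_j), "patient_id")
  expect_true(all(unlist(j2[comp]) >= unlist(base_j[comp])))
})

test_that("fulfillment equals the disjunction of components, exhaustively", {
  # independent input fragments, each activating exactly one component
  jong_frag <- list(
    c1_two_family_cancers_under18 = function(id) rbind(
      relative_event(id, "cz1", "cousin", "maternal", "leukemia", 10),
      relative_event(id, "cz2", "cousin", "maternal", "sarcoma", 12)),
    c1_first_degree_under45 = function(id)
      relative_event(id, "mo", "mother", "not_applicable", "melanoma", 40),
    c1_two_relatives_same_lineage_under45 = function(id) rbind(
      relative_event(id, "a1", "aunt", "paternal", "melanoma", 40),
      relative_event(id, "a2", "aunt", "paternal", "melanoma", 43)),
    c1_consanguinity = function(id)
      relative_event(id, "gf", "grandfather", "maternal", NA, NA,
                     consang = TRUE))
  jong_flags <- c(c2_indicative_neoplasm = "neoplasm_in_jongmans_c2_list",
                  c3_tumor_analysis = "tumor_analysis_suggests_germline",
                  c4_multiple_malignancies = "multiple_primaries")
  comp_names <- c(names(jong_frag), names(jong_flags), "c5_phenotype")
  for (mask in 0:(2^8 - 1)) {
    on <- comp_names[bitwAnd(mask, 2^(seq_len(8) - 1)) > 0]
    fam <- do.call(rbind, c(list(empty_family()),
                            lapply(intersect(on, names(jong_frag)),
                                   function(k) jong_frag[[k]]("PX"))))
    p <- one_proband(
      id = "PX",
      tumor_flags = paste(jong_flags[intersect(on, names(jong_flags))],
                          collapse = ","),
      phenotype_flags = if ("c5_phenotype" %in% on) "growth_anomalies" else "")
    j <- evaluate_jongmans(p, fam)
    expect_equal(unlist(j[comp_names]) > 0, comp_names %in% on,
                 ignore_attr = TRUE)
    expect_equal(j$jongmans_fulfilled, length(on) > 0)
  }
})

test_that("MIPOGG fulfillment equals the disjunction of its components", {
  frag <- list(
    family_known_cps = function(id)
      relative_event(id, "gm", "grandmother", "maternal", NA, NA,
                     known_cps = TRUE),
    family_close_under18_or_parent_sib_under50 = function(id)
      relative_event(id, "fa", "father", "not_applicable",
                     "colon cancer", 49),
    family_same_type_or_organ = function(id)
      relative_event(id, "gf", "grandfather", "maternal", "lymphoma", 60),
    family_multiple_primaries = function(id) rbind(
      relative_event(id, "gf2", "grandfather", "paternal", "melanoma", 60),
      relative_event(id, "gf2", "grandfather", "paternal", "lung cancer", 65)))
  flags <- c(direct_referral_tumor = "neoplasm_in_mipogg_direct_list",
             anamnestic_multiple_primaries = "multiple_primaries",
             anamnestic_bilateral_multifocal = "bilateral_or_multifocal")
  comp_names <- c(names(flags), "anamnestic_dysmorphic", names(frag))
  for (mask in 0:(2^8 - 1)) {
    on <- comp_names[bitwAnd(mask, 2^(seq_len(8) - 1)) > 0]
    fam <- do.call(rbind, c(list(empty_family()),
                            lapply(intersect(on, names(frag)),
                                   function(k) frag[[k]]("PX"))))
    p <- one_proband(
      "lymphoma", id = "PX",
      tumor_flags = paste(flags[intersect(on, names(flags))], collapse = ","),
      phenotype_flags = if ("anamnestic_dysmorphic" %in% on)
        "dysmorphic_cancer_related" else "")
    m <- evaluate_mipogg(p, fam)
    expect_equal(unlist(m[comp_names]) > 0, comp_names %in% on,
                 ignore_attr = TRUE)
    expect_equal(m$mipogg_referral, length(on) > 0)
  }
})

test_that("concordance flags and counts agree with hand-computed cases", {
  pro <- proband_table(c("P1", "P2"), "male", c(4L, 6L),
                       c("medulloblastoma", "Wilms tumor"))
  fam <- rbind(
    relative_event("P1", "gm", "grandmother", "maternal", "glioblastoma", 60),
    relative_event("P2", "aunt", "aunt", "paternal", "retinoblastoma", 1))
  cs <- concordance_summary(pro, fam)
  expect_true(all(cs$per_proband$same_organ_system_as_proband))
  expect_true(cs$per_proband$family_CNS[1])
  expect_true(cs$per_proband$family_solid_defined[2])
  expect_true(cs$per_proband$family_cancer_under18[2])
  expect_equal(unname(cs$counts["any_family_cancer"]), 2)
  # cohort counts equal the sum of per-proband flags
  expect_equal(unname(cs$counts),
               unname(colSums(cs$per_proband[-1])))
  # no relatives: all zero
  cs0 <- concordance_summary(pro, empty_family())
  expect_equal(sum(cs0$counts), 0)
})

test_that("verification accounting matches the printed worked example", {
  vs <- verification_summary(704, 106, 45, 225)
  expect_equal(vs$verified_count, 328)
  expect_equal(vs$remaining, 598)
  expect_equal(round(vs$verified_fraction_of_remaining, 3), 0.548)
  expect_equal(verification_summary(10, 0, 0, 0),
               list(verified_count = 10, remaining = 10,
                    verified_fraction_of_remaining = 1.0))
  deg <- verification_summary(10, 10, 0, 0)
  expect_equal(deg$verified_count, 0)
  expect_true(is.na(deg$verified_fraction_of_remaining))
  expect_error(verification_summary(10, 0, 8, 8), "negative")
})
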