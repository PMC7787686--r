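# Clinical-criteria rule engines over three-generation pedigrees.
#
# Jongmans' criteria 1-5 are implemented (criterion 6, excessive treatment
# toxicity, is deliberately not part of the rule set). MIPOGG is the
# universal anamnestic/family rules plus the direct-referral tumor list.
# Family cancer events count toward criteria only when they were known at
# the proband's diagnosis and are malignant.

criteria_events <- function(fam) {
  fam[!is.na(fam$diagnosis) & fam$malignant &
        fam$known_at_proband_diagnosis, , drop = FALSE]
}

# side of the family a relative contributes to for lineage-pooled rules:
# the father/mother define their own lineage, siblings pool with neither.
rule_lineage <- function(relation, lineage) {
  out <- lineage
  out[relation == "father"] <- "paternal"
  out[relation == "mother"] <- "maternal"
  out[relation %in% c("sibling")] <- "not_applicable"
  out
}

#' Evaluate Jongmans' criteria for one proband
#'
#' Per-criterion booleans:
#' * `c1_two_family_cancers_under18`: two or more malignancies in family
#'   members before age 18 (events, not relatives, are counted).
#' * `c1_first_degree_under45`: any first-degree relative with cancer
#'   before 45.
#' * `c1_two_relatives_same_lineage_under45`: two or more 1st/2nd-degree
#'   relatives in the same parental lineage with cancer before 45
#'   (maternal and paternal sides are never pooled).
#' * `c1_consanguinity`: consanguineous parents.
#' * `c2_indicative_neoplasm`: the diagnosis itself indicates a CPS.
#' * `c3_tumor_analysis`: tumor analysis suggests germline predisposition.
#' * `c4_multiple_malignancies`: secondary, bilateral, multifocal or
#'   metachronous cancers.
#' * `c5_phenotype`: any checklist phenotype finding.
#'
#' @param proband One row of a proband table.
#' @param relatives Family-table rows of the proband's family.
#' @param indicative Diagnosis list for criterion 2
#'   (default [jongmans_indicative_neoplasms()]).
#' @return One-row data.frame of the component booleans plus
#'   `jongmans_fulfilled`.
#' @export
evaluate_jongmans <- function(proband, relatives,
                              indicative = jongmans_indicative_neoplasms()) {
  ev <- criteria_events(relatives)
  deg <- if (nrow(ev)) relationship_degree(ev$relation) else integer(0)
  under45 <- !is.na(ev$age_at_diagnosis) & ev$age_at_diagnosis < 45
  under18 <- !is.na(ev$age_at_diagnosis) & ev$age_at_diagnosis < 18

  c1a <- sum(under18) >= 2
  c1b <- any(deg == 1 & under45)
  side <- rule_lineage(ev$relation, ev$lineage)
  pool <- deg <= 2 & under45 & side %in% c("maternal", "paternal")
  per_side <- tapply(ev$relative_id[pool], side[pool],
                     function(r) length(unique(r)))
  c1c <- length(per_side) > 0 && any(per_side >= 2)
  c1d <- isTRUE(any(relatives$consanguineous))

  dx <- normalize_diagnosis(proband$diagnosis)
  c2 <- dx %in% normalize_diagnosis(indicative) ||
    has_flag(proband$tumor_flags, "neoplasm_in_jongmans_c2_list")
  c3 <- has_flag(proband$tumor_flags, "tumor_analysis_suggests_germline")
  c4 <- has_flag(proband$tumor_flags, "multiple_primaries") ||
    has_flag(proband$tumor_flags, "bilateral_or_multifocal")
  c5 <- length(string_to_flags(proband$phenotype_flags)[[1]]) > 0

  data.frame(patient_id = proband$patient_id,
             c1_two_family_cancers_under18 = c1a,
             c1_first_degree_under45 = c1b,
             c1_two_relatives_same_lineage_under45 = c1c,
             c1_consanguinity = c1d,
             c2_indicative_neoplasm = c2,
             c3_tumor_analysis = c3,
             c4_multiple_malignancies = c4,
             c5_phenotype = c5,
             jongmans_fulfilled = c1a || c1b || c1c || c1d || c2 || c3 ||
               c4 || c5,
             stringsAsFactors = FALSE)
}

#' Evaluate MIPOGG referral logic for one proband
#'
#' Universal anamnestic criteria (more than one primary tumor,
#' bilateral/multifocal tumors, dysmorphic features deemed related to
#' cancer predisposition), family criteria over close relatives (degree
#' <= `close_degree`), and the direct-referral tumor list. The family age
#' rule is: a close relative with cancer before 18, or a
#' parent/sibling/half-sibling with cancer before 50.
#'
#' @inheritParams evaluate_jongmans
#' @param direct Diagnosis list for direct referral
#'   (default [mipogg_direct_referral_tumors()]).
#' @param close_degree Maximum relationship degree of a "close" relative.
#' @return One-row data.frame of component booleans plus `mipogg_referral`.
#' @export
evaluate_mipogg <- function(proband, relatives,
                            direct = mipogg_direct_referral_tumors(),
                            close_degree = 2) {
  ev <- criteria_events(relatives)
  deg <- if (nrow(ev)) relationship_degree(ev$relation) else integer(0)
  close <- deg <= close_degree
  under18 <- !is.na(ev$age_at_diagnosis) & ev$age_at_diagnosis < 18
  under50 <- !is.na(ev$age_at_diagnosis) & ev$age_at_diagnosis < 50
  parent_sib <- ev$relation %in% c("mother", "father", "sibling",
                                   "half_sibling")

  dx <- normalize_diagnosis(proband$diagnosis)
  direct_tumor <- dx %in% normalize_diagnosis(direct) ||
    has_flag(proband$tumor_flags, "neoplasm_in_mipogg_direct_list")
  multi_prim <- has_flag(proband$tumor_flags, "multiple_primaries")
  bilateral <- has_flag(proband$tumor_flags, "bilateral_or_multifocal")
  dysmorphic <- has_flag(proband$phenotype_flags, "dysmorphic_cancer_related")

  fam_cps <- isTRUE(any(relatives$known_cps))
  fam_age <- any(close & under18) || any(parent_sib & under50)
  pr_organ <- organ_group(proband$diagnosis)
  ev_organ <- if (nrow(ev)) organ_group(ev$diagnosis) else character(0)
  specific <- setdiff(.organ_levels, "other")
  fam_organ <- any(close & ev_organ == pr_organ & ev_organ %in% specific)
  n_ev_close <- tapply(rep(1, sum(close)), ev$relative_id[close], sum)
  fam_multi <- length(n_ev_close) > 0 && any(n_ev_close >= 2)

  data.frame(patient_id = proband$patient_id,
             direct_referral_tumor = direct_tumor,
             anamnestic_multiple_primaries = multi_prim,
             anamnestic_bilateral_multifocal = bilateral,
             anamnestic_dysmorphic = dysmorphic,
             family_known_cps = fam_cps,
             family_close_under18_or_parent_sib_under50 = fam_age,
             family_same_type_or_organ = fam_organ,
             family_multiple_primaries = fam_multi,
             mipogg_referral = direct_tumor || multi_prim || bilateral ||
               dysmorphic || fam_cps || fam_age || fam_organ || fam_multi,
             stringsAsFactors = FALSE)
}

#' Criteria outcomes for a whole cohort
#'
#' Runs both rule engines on every proband. `recorded` supplies stored
#' per-patient outcomes for cases whose underlying inputs are not available
#' (e.g. encoded historical records): for those patients the recorded
#' fulfillment flags replace the computed ones and `recorded` is `TRUE`.
#'
#' @param probands A proband table.
#' @param relatives A family table (matched on `family_id`).
#' @param recorded Optional data.frame with `patient_id`, `jongmans`,
#'   `mipogg`.
#' @inheritParams evaluate_jongmans
#' @inheritParams evaluate_mipogg
#' @return A data.frame, one row per proband, with all component booleans,
#'   `jongmans_fulfilled`, `mipogg_referral` and `recorded`.
#' @export
criteria_outcomes <- function(probands, relatives, recorded = NULL,
                              indicative = jongmans_indicative_neoplasms(),
                              direct = mipogg_direct_referral_tumors(),
                              close_degree = 2) {
  probands <- validate_probands(probands)
  relatives <- validate_family(relatives)
  rows <- lapply(seq_len(nrow(probands)), function(i) {
    p <- probands[i, , drop = FALSE]
    fam <- relatives[relatives$family_id == p$family_id, , drop = FALSE]
    j <- evaluate_jongmans(p, fam, indicative)
    m <- evaluate_mipogg(p, fam, direct, close_degree)
    cbind(j, m[setdiff(names(m), "patient_id")])
  })
  out <- do.call(rbind, rows)
  out$recorded <- FALSE
  if (!is.null(recorded) && nrow(recorded)) {
    idx <- match(recorded$patient_id, out$patient_id)
    ok <- !is.na(idx)
    out$jongmans_fulfilled[idx[ok]] <- recorded$jongmans[ok]
    out$mipogg_referral[idx[ok]] <- recorded$mipogg[ok]
    out$recorded[idx[ok]] <- TRUE
  }
  out
}

#' Family-history concordance summary
#'
#' Per-proband pedigree flags over 1st-3rd-degree relatives (all malignant
#' events, whether or not known at diagnosis) and their cohort-level
#' counts:
#' any family cancer, a family cancer before 18, a relative diagnosed
#' between 18 and 45, two or more same-lineage 1st/2nd-degree relatives
#' under 45, a relative with a cancer of the same organ system as the
#' proband, and per-organ-group flags.
#'
#' @param probands A proband table.
#' @param relatives A family table.
#' @return An object of class `concordance_summary`: list with
#'   `per_proband` (data.frame) and `counts` (named integer vector).
#' @export
concordance_summary <- function(probands, relatives) {
  probands <- validate_probands(probands)
  relatives <- validate_family(relatives)
  group_match <- c(hematologic = "hematologic", CNS = "CNS",
                   solid = "solid_defined")
  rows <- lapply(seq_len(nrow(probands)), function(i) {
    p <- probands[i, , drop = FALSE]
    fam <- relatives[relatives$family_id == p$family_id, , drop = FALSE]
    ev <- fam[!is.na(fam$diagnosis) & fam$malignant, , drop = FALSE]
    deg <- if (nrow(ev)) relationship_degree(ev$relation) else integer(0)
    ev <- ev[deg <= 3, , drop = FALSE]
    og <- if (nrow(ev)) organ_group(ev$diagnosis) else character(0)
    age <- ev$age_at_diagnosis
    side <- rule_lineage(ev$relation, ev$lineage)
    u45 <- !is.na(age) & age < 45
    pool <- relationship_degree(ev$relation) <= 2 & u45 &
      side %in% c("maternal", "paternal")
    per_side <- tapply(ev$relative_id[pool], side[pool],
                       function(r) length(unique(r)))
    data.frame(
      patient_id = p$patient_id,
      any_family_cancer = nrow(ev) > 0,
      family_cancer_under18 = any(!is.na(age) & age < 18),
      relative_18_to_45 = any(!is.na(age) & age >= 18 & age <= 45),
      two_or_more_under45_same_lineage =
        length(per_side) > 0 && any(per_side >= 2),
      same_organ_system_as_proband =
        any(og == group_match[[p$diagnosis_group]]),
      family_hematologic = any(og == "hematologic"),
      family_CNS = any(og == "CNS"),
      family_solid_defined = any(og == "solid_defined"),
      family_breast = any(og == "breast"),
      family_gastrointestinal = any(og == "gastrointestinal"),
      stringsAsFactors = FALSE)
  })
  per <- do.call(rbind, rows)
  counts <- colSums(per[setdiff(names(per), "patient_id")])
  structure(list(per_proband = per, counts = counts),
            class = "concordance_summary")
}

#' @export
print.concordance_summary <- function(x, ...) {
  cat("Family-history concordance over", nrow(x$per_proband), "probands\n")
  for (nm in names(x$counts)) {
    cat(sprintf("  %-38s %d\n", nm, x$counts[[nm]]))
  }
  invisible(x)
}

#' Family-history verification accounting
#'
#' Family members residing abroad cannot be verified and leave the
#' denominator; of the remaining, those who declined consent or whose
#' diagnoses could not be found in the registries stay unverified.
#'
#' @param reported Total family members with reported cancer diagnoses.
#' @param abroad Number residing abroad (removed from the denominator).
#' @param declined Number declining record retrieval.
#' @param unverifiable Number whose diagnoses could not be verified.
#' @return List with `verified_count`, `remaining` and
#'   `verified_fraction_of_remaining` (NA when no one remains).
#' @export
#' @examples
#' verification_summary(704, 106, 45, 225)
verification_summary <- function(reported, abroad, declined, unverifiable) {
  stopifnot(reported >= 0, abroad >= 0, declined >= 0, unverifiable >= 0)
  if (abroad > reported) stop("abroad exceeds reported family members")
  remaining <- reported - abroad
  verified <- remaining - declined - unverifiable
  if (verified < 0) stop("inconsistent accounting: negative verified count")
  list(verified_count = verified,
       remaining = remaining,
       verified_fraction_of_remaining =
         if (remaining == 0) NA_real_ else verified / remaining)
}
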