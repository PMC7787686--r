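# CPS classification: onset category, zygosity, trio inheritance, and the
# tiered suspicion scheme.
#
# Tier precedence (each patient counted once, highest applicable):
#   confirmed_childhood > confirmed_adult > biallelic_carrier >
#   criteria_only > family_history_only > none.

.qualifying_events <- c("trisomy_21", "upd_11p")

#' Assign parental origin from trio genotypes
#'
#' @param child_gt,mother_gt,father_gt Genotypes as `"ref"`, `"het"` or
#'   `"hom_alt"`; a missing parent is `NA`.
#' @return One of `"maternal"`, `"paternal"`, `"de_novo"`, `"unknown"`.
#' @export
#' @examples
#' assign_inheritance("het", "het", "ref")  # maternal
#' assign_inheritance("het", "ref", "ref")  # de novo
assign_inheritance <- function(child_gt, mother_gt, father_gt) {
  stopifnot(length(child_gt) == 1)
  if (is.na(child_gt) || child_gt == "ref") {
    stop("child does not carry the variant: inheritance is undefined")
  }
  carries <- function(g) !is.na(g) & g %in% c("het", "hom_alt")
  if (is.na(mother_gt) || is.na(father_gt)) return("unknown")
  m <- carries(mother_gt)
  f <- carries(father_gt)
  if (m && f) return("unknown")
  if (m) return("maternal")
  if (f) return("paternal")
  "de_novo"
}

#' Onset category of a pathogenic variant
#'
#' The variant-level curated onset override wins over the gene's default
#' onset (some variants in childhood-onset genes are associated only with
#' adult-onset disease).
#'
#' @param variants A variant table (with `onset_override` from
#'   [apply_curation()]; absent overrides count as `"none"`).
#' @param panel A panel table.
#' @return Character vector, `"childhood"` or `"adult"` (NA off panel).
#' @export
assign_onset <- function(variants, panel) {
  onset <- panel$onset_default[match(variants$gene, panel$symbol)]
  ov <- variants$onset_override
  if (is.null(ov)) ov <- rep("none", nrow(variants))
  ifelse(!is.na(ov) & ov %in% c("childhood", "adult"), ov, onset)
}

#' Zygosity note for a patient's PVs in one gene
#'
#' Two heterozygous PVs with opposite parental origins are confirmed in
#' trans; two without phase evidence are phase-unknown; a single
#' heterozygous PV is monoallelic. A homozygous PV counts as a biallelic
#' pair.
#'
#' @param inheritances Character vector of parental origins of the PVs.
#' @param genotypes Character vector of genotypes (`"het"`/`"hom_alt"`).
#' @return One of `"monoallelic"`, `"biallelic_confirmed_trans"`,
#'   `"biallelic_phase_unknown"`.
#' @export
resolve_zygosity <- function(inheritances, genotypes = rep("het", length(inheritances))) {
  stopifnot(length(inheritances) >= 1)
  if (any(genotypes == "hom_alt")) return("biallelic_confirmed_trans")
  if (length(inheritances) == 1) return("monoallelic")
  if (any(inheritances %in% c("maternal", "de_novo")) &&
      any(inheritances == "paternal")) {
    return("biallelic_confirmed_trans")
  }
  if (all(inheritances == "maternal") || all(inheritances == "paternal")) {
    # both alleles traced to the same parent: still a pair, phase in cis
    # cannot be excluded
    return("biallelic_phase_unknown")
  }
  "biallelic_phase_unknown"
}

#' Assign every proband a suspicion tier
#'
#' Combines triaged PVs, chromosomal events, gene inheritance mode and
#' zygosity, clinical-criteria outcomes and family-history flags into one
#' tier per patient:
#'
#' * `confirmed_childhood`: any childhood-onset PV consistent with the
#'   gene's inheritance mode (one PV in a monoallelic-mode CPS gene, or a
#'   biallelic / phase-unknown pair in a recessive childhood gene), or a
#'   qualifying chromosomal event (trisomy 21, UPD 11p).
#' * `confirmed_adult`: any adult-onset PV in a monoallelic-mode CPS gene.
#' * `biallelic_carrier`: only heterozygous PVs in biallelic-mode CPS
#'   genes.
#' * `criteria_only`: Jongmans' criteria or MIPOGG fulfilled.
#' * `family_history_only`: a family history of cancer without any of the
#'   above.
#' * `none` otherwise.
#'
#' Only CPS genes (cancer-314 membership) confer tiers; PVs in
#' actionable-only genes are secondary findings.
#'
#' @param probands A proband table.
#' @param triage Output of [run_triage()].
#' @param panel A panel table.
#' @param criteria Output of [criteria_outcomes()] (may be `NULL`).
#' @param family_flags Optional data.frame with `patient_id` and
#'   `any_family_cancer` (see [concordance_summary()]).
#' @return A data.frame with one row per proband: `tier`, `multi_pv`,
#'   `n_findings`, `contributing_findings`, `zygosity_notes`,
#'   `has_adult_pv`, `has_biallelic_gene_pv`, `phase_caveat`.
#' @export
classify_cohort <- function(probands, triage, panel, criteria = NULL,
                            family_flags = NULL) {
  probands <- validate_probands(probands)
  pv <- triage[triage$status == "pv", , drop = FALSE]
  pv$onset <- assign_onset(pv, panel)

  out <- data.frame(patient_id = probands$patient_id,
                    stringsAsFactors = FALSE)
  n <- nrow(out)
  tier <- rep("none", n)
  multi <- logical(n); nfind <- integer(n)
  contributing <- character(n); zyg <- character(n)
  has_adult <- logical(n); has_biallelic <- logical(n)
  caveat <- logical(n)

  crit_ok <- rep(FALSE, n)
  if (!is.null(criteria)) {
    m <- match(probands$patient_id, criteria$patient_id)
    crit_ok <- !is.na(m) &
      (criteria$jongmans_fulfilled[m] | criteria$mipogg_referral[m])
    crit_ok[is.na(crit_ok)] <- FALSE
  }
  fam_ok <- rep(FALSE, n)
  if (!is.null(family_flags)) {
    m <- match(probands$patient_id, family_flags$patient_id)
    fam_ok <- !is.na(m) & family_flags$any_family_cancer[m]
    fam_ok[is.na(fam_ok)] <- FALSE
  }

  for (i in seq_len(n)) {
    pid <- probands$patient_id[i]
    vp <- pv[!is.na(pv$patient_id) & pv$patient_id == pid &
               is.na(pv$event), , drop = FALSE]
    cps <- vp[!is.na(vp$gene) &
                vp$gene %in% panel$symbol[panel$in_cancer314], , drop = FALSE]
    events <- intersect(string_to_flags(probands$chromosomal_events[i])[[1]],
                        .qualifying_events)

    childhood <- length(events) > 0
    adult <- FALSE
    carrier <- FALSE
    notes <- character(0)
    findings <- c(vp$variant_key, events)

    if (nrow(cps)) {
      for (g in unique(cps$gene)) {
        vg <- cps[cps$gene == g, , drop = FALSE]
        mode <- panel$inheritance_mode[match(g, panel$symbol)]
        z <- resolve_zygosity(vg$inheritance, vg$genotype)
        notes <- c(notes, paste0(g, "=", z))
        pair <- z != "monoallelic"
        onsets <- unique(vg$onset)
        if (mode %in% c("monoallelic", "both")) {
          if ("childhood" %in% onsets) childhood <- TRUE
          if ("adult" %in% onsets) {adult <- TRUE; has_adult[i] <- TRUE}
        } else { # biallelic-mode gene
          has_biallelic[i] <- TRUE
          if (pair) {
            if ("childhood" %in% onsets) {
              childhood <- TRUE
              if (z == "biallelic_phase_unknown") caveat[i] <- TRUE
            }
            if ("adult" %in% onsets) adult <- TRUE
          } else {
            carrier <- TRUE
          }
        }
      }
    }

    # trisomy 21 counts as a single finding however it was recorded
    n_findings <- nrow(vp) + length(events)
    tier[i] <- if (childhood) "confirmed_childhood"
      else if (adult) "confirmed_adult"
      else if (carrier) "biallelic_carrier"
      else if (crit_ok[i]) "criteria_only"
      else if (fam_ok[i]) "family_history_only"
      else "none"
    multi[i] <- n_findings >= 2
    nfind[i] <- n_findings
    contributing[i] <- paste(findings, collapse = ",")
    zyg[i] <- paste(notes, collapse = ";")
  }

  out$tier <- tier
  out$multi_pv <- multi
  out$n_findings <- nfind
  out$contributing_findings <- contributing
  out$zygosity_notes <- zyg
  out$has_adult_pv <- has_adult
  out$has_biallelic_gene_pv <- has_biallelic
  out$phase_caveat <- caveat
  out$jongmans_fulfilled <- if (!is.null(criteria))
    criteria$jongmans_fulfilled[match(out$patient_id, criteria$patient_id)]
    else NA
  out$mipogg_referral <- if (!is.null(criteria))
    criteria$mipogg_referral[match(out$patient_id, criteria$patient_id)]
    else NA
  out
}

#' Patients carrying two or more pathogenic findings
#'
#' Counts PVs plus chromosomal events, with trisomy 21 counted once
#' regardless of how it was recorded.
#'
#' @param assignments Output of [classify_cohort()].
#' @return The rows of `assignments` with `multi_pv`, sorted by patient id.
#' @export
detect_multi_pv <- function(assignments) {
  out <- assignments[assignments$multi_pv, , drop = FALSE]
  out[order(out$patient_id), , drop = FALSE]
}
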