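# Cohort summarization, contingency testing, disclosure filtering and
# report rendering.

#' Pearson chi-square test on a contingency table
#'
#' Standard Pearson statistic against margin-derived expected counts, with
#' an optional Yates continuity correction for 2x2 tables. The default is
#' no correction. Two-sided p-value from the chi-square distribution with
#' (r-1)(c-1) degrees of freedom.
#'
#' @param table An r x c matrix of nonnegative counts (r, c >= 2).
#' @param continuity_correction Apply the Yates correction (2x2 only).
#' @return An object of class `contingency_test` with elements `table`,
#'   `statistic`, `df`, `p`, `expected`, `continuity_correction`.
#' @export
#' @examples
#' pearson_chi2(matrix(c(2, 17, 7, 4), 2))
pearson_chi2 <- function(table, continuity_correction = FALSE) {
  table <- as.matrix(table)
  if (nrow(table) < 2 || ncol(table) < 2) stop("table must be at least 2x2")
  if (any(table < 0) || any(table != round(table))) {
    stop("counts must be nonnegative integers")
  }
  if (any(rowSums(table) == 0) || any(colSums(table) == 0)) {
    stop("zero margin: the test is undefined")
  }
  ht <- suppressWarnings(stats::chisq.test(table,
                                           correct = continuity_correction))
  structure(list(table = table,
                 statistic = unname(ht$statistic),
                 df = unname(ht$parameter),
                 p = unname(ht$p.value),
                 expected = ht$expected,
                 continuity_correction = continuity_correction),
            class = "contingency_test")
}

#' @export
print.contingency_test <- function(x, ...) {
  cat("Pearson chi-square",
      if (x$continuity_correction) "(Yates-corrected)" else "(no correction)",
      "\n")
  cat(sprintf("  X-squared = %.4g, df = %d, p = %.4g\n",
              x$statistic, x$df, x$p))
  invisible(x)
}

# percentage rendering used throughout the report: one decimal,
# round half away from zero
format_pct <- function(x) {
  sprintf("%.1f%%", floor(abs(x) * 10 + 0.5) / 10 * sign(x))
}

#' Summarize a classified cohort
#'
#' Tier counts and fractions of the suspicion triangle, clinical-criteria
#' fulfillment overall and within patient groups, multi-PV carriers, and
#' the count of patients carrying any biallelic-CPS-gene PV.
#'
#' Group fulfillment follows the patient-counting convention of the tier
#' scheme: the childhood-onset group is the `confirmed_childhood` tier; the
#' adult-onset group comprises every carrier of an adult-onset PV, but a
#' patient counted in the childhood tier does not contribute fulfillment to
#' the adult group (their fulfillment is attributed to the childhood
#' syndrome).
#'
#' @param assignments Output of [classify_cohort()].
#' @param criteria Output of [criteria_outcomes()].
#' @param concordance Optional [concordance_summary()].
#' @return An object of class `cps_cohort_summary`.
#' @export
summarize_cohort <- function(assignments, criteria, concordance = NULL) {
  if (!setequal(assignments$patient_id, criteria$patient_id)) {
    stop("assignments and criteria cover different patients")
  }
  m <- match(assignments$patient_id, criteria$patient_id)
  jong <- criteria$jongmans_fulfilled[m]
  mip <- criteria$mipogg_referral[m]
  either <- jong | mip
  n <- nrow(assignments)

  tier_counts <- vapply(.tier_levels, function(t)
    sum(assignments$tier == t), integer(1))
  stopifnot(sum(tier_counts) == n)

  child <- assignments$tier == "confirmed_childhood"
  adult_tier <- assignments$tier == "confirmed_adult"
  adult_group <- assignments$has_adult_pv
  carrier <- assignments$tier == "biallelic_carrier"

  grp <- function(num, den) {
    list(fulfilled = sum(num), n = sum(den),
         pct = if (sum(den) == 0) NA_real_ else 100 * sum(num) / sum(den))
  }
  groups <- list(
    childhood_jongmans = grp(child & jong, child),
    childhood_mipogg = grp(child & mip, child),
    childhood_either = grp(child & either, child),
    adult_jongmans = grp(adult_tier & jong, adult_group),
    adult_mipogg = grp(adult_tier & mip, adult_group),
    adult_either = grp(adult_tier & either, adult_group),
    carrier_jongmans = grp(carrier & jong, carrier),
    carrier_mipogg = grp(carrier & mip, carrier),
    carrier_either = grp(carrier & either, carrier))

  structure(list(
    n = n,
    tier_counts = tier_counts,
    tier_fractions = tier_counts / n,
    confirmed_cps = unname(tier_counts["confirmed_childhood"] +
                             tier_counts["confirmed_adult"]),
    adult_pv_carriers = sum(adult_group),
    biallelic_gene_pv_carriers = sum(assignments$has_biallelic_gene_pv),
    multi_pv = sum(assignments$multi_pv),
    suspected_any = n - unname(tier_counts["none"]),
    jongmans_fulfilled = sum(jong),
    mipogg_referral = sum(mip),
    either_fulfilled = sum(either),
    groups = groups,
    concordance = if (is.null(concordance)) NULL else concordance$counts),
    class = "cps_cohort_summary")
}

#' @export
print.cps_cohort_summary <- function(x, ...) {
  cat("CPS screening cohort summary (n = ", x$n, ")\n", sep = "")
  cat("Suspicion triangle (each patient counted once, top-most tier):\n")
  for (t in names(x$tier_counts)) {
    cat(sprintf("  %-22s %3d (%s)\n", t, x$tier_counts[[t]],
                format_pct(100 * x$tier_fractions[[t]])))
  }
  cat(sprintf("Confirmed CPS: %d (%s); multi-PV carriers: %d (%s)\n",
              x$confirmed_cps, format_pct(100 * x$confirmed_cps / x$n),
              x$multi_pv, format_pct(100 * x$multi_pv / x$n)))
  cat(sprintf("Any biallelic-CPS-gene PV: %d (%s)\n",
              x$biallelic_gene_pv_carriers,
              format_pct(100 * x$biallelic_gene_pv_carriers / x$n)))
  cat(sprintf("Criteria: Jongmans %d, MIPOGG %d, either %d (%s)\n",
              x$jongmans_fulfilled, x$mipogg_referral, x$either_fulfilled,
              format_pct(100 * x$either_fulfilled / x$n)))
  g <- x$groups
  cat(sprintf("Jongmans among childhood-onset CPS: %d/%d (%s)\n",
              g$childhood_jongmans$fulfilled, g$childhood_jongmans$n,
              format_pct(g$childhood_jongmans$pct)))
  cat(sprintf("Jongmans among adult-onset CPS:     %d/%d (%s)\n",
              g$adult_jongmans$fulfilled, g$adult_jongmans$n,
              format_pct(g$adult_jongmans$pct)))
  invisible(x)
}

#' Disclosure filtering by feedback level
#'
#' Families choose one of three feedback levels: level 1 discloses PVs in
#' ACMG actionable genes only; level 2 adds PVs in the cancer-gene panel;
#' level 3 adds remaining findings. Heterozygous PVs in genes with solely
#' recessive (biallelic) inheritance are withheld unless further familial
#' testing is warranted; this applies at every level, so disclosure sets
#' are nested across levels. Findings in CPS genes are tagged primary,
#' others secondary.
#'
#' @param findings Triaged PV rows (a variant table with `status == "pv"`).
#' @param feedback_level 1, 2 or 3.
#' @param panel A panel table.
#' @param familial_testing_warranted Logical scalar or vector (per
#'   finding): carrier findings flagged `TRUE` are disclosed.
#' @return An object of class `disclosure_report`: the findings with
#'   `disclosed`, `tag` (`"primary"`/`"secondary"`) and `withheld_reason`.
#' @export
disclose_findings <- function(findings, feedback_level, panel,
                              familial_testing_warranted = FALSE) {
  stopifnot(feedback_level %in% 1:3)
  idx <- match(findings$gene, panel$symbol)
  actionable <- !is.na(idx) & panel$actionable[idx]
  cps_gene <- !is.na(idx) & panel$in_cancer314[idx]
  recessive <- !is.na(idx) & panel$inheritance_mode[idx] == "biallelic"
  fam <- rep_len(familial_testing_warranted, nrow(findings))

  in_scope <- if (feedback_level == 1) actionable
    else if (feedback_level == 2) actionable | cps_gene
    else rep(TRUE, nrow(findings))
  carrier_only <- recessive & findings$genotype == "het" & !fam
  disclosed <- in_scope & !carrier_only

  reason <- rep(NA_character_, nrow(findings))
  reason[!in_scope] <- "outside_feedback_level"
  reason[in_scope & carrier_only] <- "recessive_carrier"

  findings$disclosed <- disclosed
  findings$tag <- ifelse(cps_gene, "primary", "secondary")
  findings$withheld_reason <- reason
  findings$feedback_level <- feedback_level
  class(findings) <- c("disclosure_report", class(findings))
  findings
}

#' Render a cohort summary
#'
#' Deterministic rendering of a [summarize_cohort()] object as
#' human-readable text or machine-readable JSON. The JSON form round-trips
#' through [parse_report_json()].
#'
#' @param summary A `cps_cohort_summary`.
#' @param format `"text"` or `"json"`.
#' @return A character scalar.
#' @export
render_report <- function(summary, format = c("text", "json")) {
  format <- match.arg(format)
  if (format == "text") {
    paste(utils::capture.output(print(summary)), collapse = "\n")
  } else {
    x <- unclass(summary)
    x$tier_counts <- as.list(x$tier_counts)
    x$tier_fractions <- as.list(x$tier_fractions)
    if (!is.null(x$concordance)) x$concordance <- as.list(x$concordance)
    as.character(jsonlite::toJSON(x, auto_unbox = TRUE, digits = NA,
                                  null = "null"))
  }
}

#' @rdname render_report
#' @param json A JSON string produced by `render_report(..., "json")`.
#' @export
parse_report_json <- function(json) {
  x <- jsonlite::fromJSON(json)
  x$tier_counts <- unlist(x$tier_counts)
  x$tier_fractions <- unlist(x$tier_fractions)
  if (!is.null(x$concordance)) x$concordance <- unlist(x$concordance)
  structure(x, class = "cps_cohort_summary")
}

#' Run the full screening pipeline on a cohort bundle
#'
#' Convenience wrapper: triage, criteria evaluation, tier classification and
#' cohort summary in one call.
#'
#' @param cohort A `cps_cohort` bundle (e.g. from [generate_cohort()]).
#' @param panel A panel table (default the packaged panel).
#' @param config A [triage_config()].
#' @param recorded Optional recorded criteria outcomes (see
#'   [criteria_outcomes()]).
#' @return List with `triage`, `criteria`, `assignments`, `concordance`,
#'   `summary`.
#' @export
run_pipeline <- function(cohort, panel = default_panel(),
                         config = triage_config(), recorded = NULL) {
  tri <- run_triage(cohort$variants, panel, cohort$curation, config)
  crit <- criteria_outcomes(cohort$probands, cohort$relatives,
                            recorded = recorded)
  conc <- concordance_summary(cohort$probands, cohort$relatives)
  fam_flags <- conc$per_proband[c("patient_id", "any_family_cancer")]
  assign <- classify_cohort(cohort$probands, tri, panel, crit, fam_flags)
  list(triage = tri, criteria = crit, assignments = assign,
       concordance = conc,
       summary = summarize_cohort(assign, crit, conc))
}
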