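# Variant triage: the filter cascade that reduces annotated germline calls
# to reportable pathogenic variants (PVs) and a VUS shortlist.
#
# Cascade order (fixed, so that reason codes are stable):
#   call quality -> consequence -> panel membership -> population frequency
#   -> classification lookup -> PV / VUS designation.
# The set-level result is order-independent; the order only determines which
# reason code an excluded variant carries (its first failing filter).

#' Call-quality filter
#'
#' A call passes when read depth, genotype quality and variant allele
#' fraction all reach their (inclusive) thresholds. Missing quality fields
#' fail: quality-missingness means the call is not trusted.
#'
#' @param variants A variant table.
#' @param config A [triage_config()].
#' @return Logical vector.
#' @export
passes_call_quality <- function(variants, config = triage_config()) {
  ok <- variants$depth >= config$min_depth &
    variants$gq >= config$min_gq &
    variants$vaf >= config$min_vaf
  ok & !is.na(ok)
}

#' Consequence filter
#'
#' Excludes intronic, intergenic and 3'/5' UTR consequences; everything
#' else, including splice donor/acceptor terms, is retained. Symbolic
#' chromosomal-event records always pass. A missing consequence is retained
#' (it cannot be proven uninteresting).
#'
#' @inheritParams passes_call_quality
#' @return Logical vector.
#' @export
passes_consequence_filter <- function(variants, config = triage_config()) {
  excluded <- !is.na(variants$consequence) &
    variants$consequence %in% config$excluded_consequences
  !excluded | !is.na(variants$event)
}

#' Population-frequency filter
#'
#' Passes variants whose maximum allele frequency in any large population is
#' strictly below the threshold; genes flagged as having high population
#' variant frequency use the alternate threshold. A missing frequency
#' passes: frequency-missingness means the variant has not been observed.
#'
#' @inheritParams passes_call_quality
#' @param panel A panel table.
#' @return Logical vector.
#' @export
passes_frequency_filter <- function(variants, panel,
                                    config = triage_config()) {
  high <- panel$symbol[panel$high_population_frequency]
  thr <- ifelse(!is.na(variants$gene) & variants$gene %in% high,
                config$max_af_high_freq_genes, config$max_af)
  af <- variants$gnomad_max_af
  af[is.na(af)] <- 0
  af < thr
}

#' Splice-effect significance
#'
#' A splice effect is significant when at least `splice_min_programs`
#' prediction programs lose at least `splice_reduction_fraction` of their
#' score, or a strong cryptic acceptor or donor site is generated. When
#' fewer programs report than the rule requires and no cryptic site exists,
#' the evidence is insufficient: the result is `FALSE` with a warning.
#'
#' @param splice_deltas Comma-joined strings (one per variant) or a numeric
#'   vector (single variant) of fractional score changes; negative values
#'   are reductions.
#' @param cryptic_site_generated Logical vector.
#' @param config A [triage_config()].
#' @return Logical vector.
#' @export
evaluate_splice_effect <- function(splice_deltas, cryptic_site_generated,
                                   config = triage_config()) {
  if (is.numeric(splice_deltas)) {
    splice_deltas <- paste(splice_deltas, collapse = ",")
  }
  deltas <- lapply(splice_deltas, function(s) {
    if (is.na(s) || !nzchar(s)) numeric(0)
    else suppressWarnings(as.numeric(strsplit(s, ",", fixed = TRUE)[[1]]))
  })
  n_prog <- lengths(deltas)
  n_hit <- vapply(deltas, function(d) {
    sum(d <= -config$splice_reduction_fraction, na.rm = TRUE)
  }, integer(1))
  insufficient <- n_prog < config$splice_min_programs &
    n_prog > 0 & !cryptic_site_generated
  if (any(insufficient)) {
    warning(sum(insufficient), " variant(s) with fewer than ",
            config$splice_min_programs,
            " splice programs reported and no cryptic site: ",
            "insufficient evidence, treated as not significant")
  }
  n_hit >= config$splice_min_programs | cryptic_site_generated
}

#' VUS shortlisting
#'
#' A retained variant enters the VUS shortlist when it is class 3, its
#' CADD-PHRED score is strictly above the threshold and its population
#' frequency is below the frequency cut-off.
#'
#' @inheritParams passes_call_quality
#' @return Logical vector.
#' @export
shortlist_vus <- function(variants, config = triage_config()) {
  af <- variants$gnomad_max_af
  af[is.na(af)] <- 0
  !is.na(variants$acmg_class) & variants$acmg_class == 3 &
    !is.na(variants$cadd_phred) &
    variants$cadd_phred > config$cadd_vus_threshold &
    af < config$max_af
}

#' Apply curation overrides to a variant table
#'
#' The curated class replaces the class carried in the VCF; variant-level
#' onset overrides are attached as an `onset_override` column.
#'
#' @param variants A variant table.
#' @param curation A curation table.
#' @return The variant table with curation applied.
#' @export
apply_curation <- function(variants, curation) {
  variants$onset_override <- "none"
  if (is.null(curation) || nrow(curation) == 0) return(variants)
  idx <- match(variants$variant_key, curation$variant_key)
  hit <- !is.na(idx)
  override_class <- curation$acmg_class[idx[hit]]
  keep <- !is.na(override_class)
  variants$acmg_class[hit][keep] <- override_class[keep]
  variants$onset_override[hit] <- curation$onset_override[idx[hit]]
  variants
}

#' Run the triage cascade
#'
#' Applies the filter cascade to every call and designates retained calls as
#' PV (curated class 4/5), VUS shortlist (class 3, high CADD, rare) or
#' retained-unclassified. Excluded calls carry the reason code of their
#' first failing filter; later filters are not evaluated for them. Splice
#' significance is recorded for all retained calls.
#'
#' @param variants A variant table.
#' @param panel A panel table.
#' @param curation A curation table (optional).
#' @param config A [triage_config()].
#' @return The variant table (after curation) with columns `status`
#'   (`"pv"`, `"vus_shortlist"`, `"retained_unclassified"`, `"excluded"`),
#'   `failed_filters` (comma-joined reason codes, empty when retained) and
#'   `splice_significant`.
#' @export
run_triage <- function(variants, panel, curation = NULL,
                       config = triage_config()) {
  variants <- validate_variants(variants)
  variants <- apply_curation(variants, curation)
  n <- nrow(variants)
  reason <- rep(NA_character_, n)
  alive <- rep(TRUE, n)

  step <- function(pass, code) {
    fail <- alive & !pass
    reason[fail] <<- code
    alive <<- alive & pass
  }
  is_event <- !is.na(variants$event)
  step(passes_call_quality(variants, config) | is_event, "call_quality")
  step(passes_consequence_filter(variants, config), "consequence")
  on_panel <- !is.na(variants$gene) & variants$gene %in% panel$symbol
  step(on_panel | is_event, "off_panel")
  step(passes_frequency_filter(variants, panel, config) | is_event,
       "frequency")

  splice <- rep(FALSE, n)
  if (any(alive)) {
    splice[alive] <- evaluate_splice_effect(
      variants$splice_deltas[alive],
      variants$cryptic_site_generated[alive], config)
  }

  status <- rep("excluded", n)
  pv <- alive & !is.na(variants$acmg_class) & variants$acmg_class %in% 4:5
  vus <- alive & shortlist_vus(variants, config)
  status[alive] <- "retained_unclassified"
  status[vus] <- "vus_shortlist"
  status[pv] <- "pv"

  variants$status <- status
  variants$failed_filters <- ifelse(is.na(reason), "", reason)
  variants$splice_significant <- splice
  variants
}
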