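#' Triage configuration
#'
#' Bundles every numeric threshold of the variant triage cascade. Defaults
#' are the study settings: calls require read depth >= 8, genotype quality
#' >= 20 and variant allele fraction >= 0.2; intronic, intergenic and UTR
#' consequences are excluded; the population-frequency cut-off is a maximum
#' allele frequency < 1% in any large gnomAD population, with a separate
#' (default 5%) threshold for genes with high carrier frequencies in the
#' general population (e.g. ATM, CHEK2); a splice effect is called
#' significant when at least three prediction programs lose >= 10% of their
#' score or a strong cryptic splice site is generated; VUS are shortlisted
#' at CADD-PHRED > 20.
#'
#' @param min_depth Minimum read depth (inclusive).
#' @param min_gq Minimum genotype quality (inclusive).
#' @param min_vaf Minimum variant allele fraction (inclusive).
#' @param max_af Population allele-frequency cut-off (exclusive).
#' @param max_af_high_freq_genes Cut-off for genes flagged as having high
#'   population variant frequency (exclusive).
#' @param cadd_vus_threshold CADD-PHRED score above which a class-3 variant
#'   enters the VUS shortlist (strict).
#' @param splice_reduction_fraction Fractional score reduction counting as a
#'   per-program splice hit.
#' @param splice_min_programs Minimum number of programs that must lose
#'   score for a splice effect to be significant.
#' @param excluded_consequences Sequence Ontology terms removed before
#'   evaluation.
#' @return A list of class `triage_config`.
#' @export
#' @examples
#' cfg <- triage_config()
#' cfg$min_depth
triage_config <- function(min_depth = 8,
                          min_gq = 20,
                          min_vaf = 0.2,
                          max_af = 0.01,
                          max_af_high_freq_genes = 0.05,
                          cadd_vus_threshold = 20,
                          splice_reduction_fraction = 0.10,
                          splice_min_programs = 3,
                          excluded_consequences = c("intron_variant",
                                                    "intergenic_variant",
                                                    "3_prime_UTR_variant",
                                                    "5_prime_UTR_variant")) {
  num <- c(min_depth = min_depth, min_gq = min_gq, min_vaf = min_vaf,
           max_af = max_af, max_af_high_freq_genes = max_af_high_freq_genes,
           cadd_vus_threshold = cadd_vus_threshold,
           splice_reduction_fraction = splice_reduction_fraction,
           splice_min_programs = splice_min_programs)
  if (any(!is.finite(num)) || any(num <= 0)) {
    stop("all triage thresholds must be strictly positive")
  }
  if (max_af_high_freq_genes < max_af) {
    stop("max_af_high_freq_genes must be >= max_af")
  }
  structure(list(min_depth = min_depth, min_gq = min_gq, min_vaf = min_vaf,
                 max_af = max_af,
                 max_af_high_freq_genes = max_af_high_freq_genes,
                 cadd_vus_threshold = cadd_vus_threshold,
                 splice_reduction_fraction = splice_reduction_fraction,
                 splice_min_programs = splice_min_programs,
                 excluded_consequences = excluded_consequences),
            class = "triage_config")
}

#' Read or write a triage configuration as YAML
#'
#' @param path File path.
#' @return `read_triage_config()` returns a `triage_config`;
#'   `write_triage_config()` returns `path` invisibly.
#' @export
read_triage_config <- function(path) {
  x <- yaml::read_yaml(path)
  do.call(triage_config, x)
}

#' @rdname read_triage_config
#' @param config A `triage_config`.
#' @export
write_triage_config <- function(config, path) {
  stopifnot(inherits(config, "triage_config"))
  yaml::write_yaml(unclass(config), path)
  invisible(path)
}
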