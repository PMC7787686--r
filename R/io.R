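# Readers and writers for the interchange formats.
#
# Annotated calls travel in VCF v4.2 with the annotation dialect carried as
# INFO keys (GENE, CSQ, GNOMAD_AF_MAX, CADD_PHRED, SPLICE_DELTAS, CRYPTIC,
# ACMG_CLASS, INHERIT, EVENT, PATIENT) and per-call quality as a single
# FORMAT column GT:DP:GQ:VAF. One record = one call of one patient, so a
# cohort file interleaves patients; PATIENT keys the record to its proband.

.vcf_info_keys <- c("PATIENT", "GENE", "CSQ", "GNOMAD_AF_MAX", "CADD_PHRED",
                    "SPLICE_DELTAS", "CRYPTIC", "ACMG_CLASS", "INHERIT",
                    "EVENT")

.known_consequences <- c(
  "missense_variant", "stop_gained", "stop_lost", "start_lost",
  "frameshift_variant", "inframe_deletion", "inframe_insertion",
  "splice_donor_variant", "splice_acceptor_variant", "splice_region_variant",
  "synonymous_variant", "intron_variant", "intergenic_variant",
  "3_prime_UTR_variant", "5_prime_UTR_variant", "feature_truncation",
  "transcript_ablation", "copy_number_gain")

#' Read an annotated germline VCF
#'
#' Parses a VCF carrying the package's annotation dialect (see
#' [write_annotated_vcf()]) into a variant table. Missing annotations map to
#' explicit `NA` markers, never silent defaults. Consequence terms outside
#' the known Sequence Ontology set raise a warning but are retained.
#'
#' @param path VCF file (may be bgzipped).
#' @return A variant table (see [variant_table()]).
#' @export
read_annotated_vcf <- function(path) {
  vcf <- tryCatch(vcfR::read.vcfR(path, verbose = FALSE),
                  error = function(e) stop("malformed VCF '", path, "': ",
                                           conditionMessage(e)))
  fix <- vcfR::getFIX(vcf)
  if (is.null(dim(fix))) fix <- t(fix)   # single-record files drop dims
  fix <- as.data.frame(fix, stringsAsFactors = FALSE)
  if (nrow(fix) == 0) {
    return(variant_table(character(0), character(0), integer(0),
                         character(0), character(0)))
  }
  info_chr <- function(key) {
    v <- unname(vcfR::extract.info(vcf, element = key))
    if (is.null(v) || length(v) == 0) rep(NA_character_, nrow(fix))
    else ifelse(v == ".", NA, v)
  }
  info_num <- function(key) suppressWarnings(as.numeric(info_chr(key)))

  gt <- vcfR::extract.gt(vcf, element = "GT")[, 1]
  dp <- suppressWarnings(as.numeric(vcfR::extract.gt(vcf, element = "DP")[, 1]))
  gq <- suppressWarnings(as.numeric(vcfR::extract.gt(vcf, element = "GQ")[, 1]))
  vaf <- suppressWarnings(as.numeric(vcfR::extract.gt(vcf, element = "VAF")[, 1]))
  genotype <- ifelse(gt %in% c("1/1", "1|1"), "hom_alt", "het")

  csq <- info_chr("CSQ")
  unknown <- setdiff(stats::na.omit(unique(csq)), .known_consequences)
  if (length(unknown)) {
    warning("unknown consequence term(s) retained: ",
            paste(unknown, collapse = ", "))
  }
  inherit <- info_chr("INHERIT")
  inherit[is.na(inherit)] <- "unknown"
  cls <- info_num("ACMG_CLASS")
  cryptic <- info_chr("CRYPTIC")
  deltas <- info_chr("SPLICE_DELTAS")
  deltas[is.na(deltas)] <- ""

  variant_table(patient_id = info_chr("PATIENT"),
                chrom = fix$CHROM, pos = as.integer(fix$POS),
                ref = fix$REF, alt = fix$ALT,
                genotype = genotype, depth = dp, gq = gq, vaf = vaf,
                gene = info_chr("GENE"), consequence = csq,
                gnomad_max_af = info_num("GNOMAD_AF_MAX"),
                cadd_phred = info_num("CADD_PHRED"),
                splice_deltas = deltas,
                cryptic_site_generated = !is.na(cryptic) & cryptic == "1",
                acmg_class = as.integer(cls), inheritance = inherit,
                event = info_chr("EVENT"))
}

#' Write an annotated germline VCF
#'
#' Serializes a variant table into the VCF dialect read by
#' [read_annotated_vcf()]; `write` then `read` round-trips the table.
#'
#' @param variants A variant table.
#' @param path Output file.
#' @return `path`, invisibly.
#' @export
write_annotated_vcf <- function(variants, path) {
  variants <- validate_variants(variants)
  esc <- function(x) ifelse(is.na(x) | x == "", ".", as.character(x))
  info <- paste0(
    "PATIENT=", esc(variants$patient_id),
    ";GENE=", esc(variants$gene),
    ";CSQ=", esc(variants$consequence),
    ";GNOMAD_AF_MAX=", esc(variants$gnomad_max_af),
    ";CADD_PHRED=", esc(variants$cadd_phred),
    ";SPLICE_DELTAS=", esc(variants$splice_deltas),
    ";CRYPTIC=", ifelse(variants$cryptic_site_generated, "1", "0"),
    ";ACMG_CLASS=", esc(variants$acmg_class),
    ";INHERIT=", esc(variants$inheritance),
    ";EVENT=", esc(variants$event))
  sample_col <- paste(ifelse(variants$genotype == "hom_alt", "1/1", "0/1"),
                      esc(variants$depth), esc(variants$gq),
                      esc(variants$vaf), sep = ":")
  header <- c(
    "##fileformat=VCFv4.2",
    "##source=cpsscreen",
    '##INFO=<ID=PATIENT,Number=1,Type=String,Description="Proband carrying the call">',
    '##INFO=<ID=GENE,Number=1,Type=String,Description="Gene symbol">',
    '##INFO=<ID=CSQ,Number=1,Type=String,Description="Sequence Ontology consequence">',
    '##INFO=<ID=GNOMAD_AF_MAX,Number=1,Type=Float,Description="Max allele frequency in any large gnomAD population">',
    '##INFO=<ID=CADD_PHRED,Number=1,Type=Float,Description="CADD-PHRED score">',
    '##INFO=<ID=SPLICE_DELTAS,Number=1,Type=String,Description="Comma list of fractional splice-program score changes">',
    '##INFO=<ID=CRYPTIC,Number=1,Type=Integer,Description="Strong cryptic splice site generated (0/1)">',
    '##INFO=<ID=ACMG_CLASS,Number=1,Type=Integer,Description="Curated ACMG class 1-5">',
    '##INFO=<ID=INHERIT,Number=1,Type=String,Description="maternal/paternal/de_novo/unknown">',
    '##INFO=<ID=EVENT,Number=1,Type=String,Description="Chromosomal event tag for symbolic records">',
    '##FORMAT=<ID=GT,Number=1,Type=String,Description="Genotype">',
    '##FORMAT=<ID=DP,Number=1,Type=Integer,Description="Read depth">',
    '##FORMAT=<ID=GQ,Number=1,Type=Integer,Description="Genotype quality">',
    '##FORMAT=<ID=VAF,Number=1,Type=Float,Description="Variant allele fraction">',
    paste("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER", "INFO",
          "FORMAT", "CALL", sep = "\t"))
  body <- paste(variants$chrom, variants$pos, ".", variants$ref, variants$alt,
                ".", "PASS", info, "GT:DP:GQ:VAF", sample_col, sep = "\t")
  writeLines(c(header, body), path)
  invisible(path)
}

.read_tsv <- function(path) {
  utils::read.delim(path, sep = "\t", header = TRUE,
                    stringsAsFactors = FALSE, na.strings = c("NA", ""),
                    colClasses = NA, check.names = FALSE)
}

.write_tsv <- function(df, path) {
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE,
                     na = "NA")
  invisible(path)
}

#' Read / write a family (pedigree) table
#'
#' The extended family TSV has one row per cancer event (or one row per
#' cancer-free relative with an empty diagnosis). Relation synonyms such as
#' "grandfather" are mapped onto the canonical vocabulary; unknown terms
#' are rejected with the offending row.
#'
#' @param path TSV file.
#' @return A validated family table, or `path` for the writer.
#' @export
read_family_table <- function(path) {
  df <- .read_tsv(path)
  for (col in c("known_at_proband_diagnosis", "malignant", "consanguineous",
                "known_cps")) {
    if (is.null(df[[col]])) {
      df[[col]] <- if (col %in% c("known_at_proband_diagnosis", "malignant"))
        TRUE else FALSE
    }
    df[[col]] <- as.logical(df[[col]])
    df[[col]][is.na(df[[col]])] <-
      col %in% c("known_at_proband_diagnosis", "malignant")
  }
  if (is.null(df$verification)) df$verification <- "reported_only"
  df$verification[is.na(df$verification)] <- "reported_only"
  df$relation <- canonical_relation(df$relation)
  df$lineage[is.na(df$lineage)] <- "not_applicable"
  validate_family(df)
}

#' @rdname read_family_table
#' @param families A family table.
#' @export
write_family_table <- function(families, path) {
  families <- validate_family(families)
  .write_tsv(families[setdiff(names(families), "degree")], path)
}

#' Read / write a gene panel table
#'
#' @param path TSV with columns symbol, cancer314, acmg59, mode, onset,
#'   high_freq, actionable.
#' @return A validated panel table (reader) or `path` (writer). The reader
#'   attaches attributes `n_cancer314` and `n_acmg59` with the membership
#'   counts.
#' @export
read_gene_panel <- function(path) {
  df <- .read_tsv(path)
  panel <- panel_table(symbol = df$symbol,
                       in_cancer314 = as.logical(df$cancer314),
                       in_acmg59 = as.logical(df$acmg59),
                       inheritance_mode = df$mode,
                       onset_default = df$onset,
                       high_population_frequency = as.logical(df$high_freq),
                       actionable = as.logical(df$actionable))
  attr(panel, "n_cancer314") <- sum(panel$in_cancer314)
  attr(panel, "n_acmg59") <- sum(panel$in_acmg59)
  panel
}

#' @rdname read_gene_panel
#' @param panel A panel table.
#' @export
write_gene_panel <- function(panel, path) {
  panel <- validate_panel(panel)
  out <- data.frame(symbol = panel$symbol,
                    cancer314 = panel$in_cancer314,
                    acmg59 = panel$in_acmg59,
                    mode = panel$inheritance_mode,
                    onset = panel$onset_default,
                    high_freq = panel$high_population_frequency,
                    actionable = panel$actionable)
  .write_tsv(out, path)
}

#' Read / write a proband table
#'
#' @param path TSV file.
#' @return A validated proband table, or `path` for the writer.
#' @export
read_proband_table <- function(path) {
  df <- .read_tsv(path)
  for (col in c("tumor_flags", "phenotype_flags", "chromosomal_events")) {
    if (is.null(df[[col]])) df[[col]] <- ""
    df[[col]][is.na(df[[col]])] <- ""
  }
  if (is.null(df$family_id)) df$family_id <- df$patient_id
  df$diagnosis_group <- diagnosis_group(df$diagnosis)
  validate_probands(df)
}

#' @rdname read_proband_table
#' @param probands A proband table.
#' @export
write_proband_table <- function(probands, path) {
  probands <- validate_probands(probands)
  .write_tsv(probands[setdiff(names(probands), "diagnosis_group")], path)
}

#' Read / write a curation table
#'
#' @param path TSV with columns variant_key, acmg_class, onset_override.
#' @return A curation table, or `path` for the writer.
#' @export
read_curation_table <- function(path) {
  df <- .read_tsv(path)
  if (is.null(df$onset_override)) df$onset_override <- "none"
  df$onset_override[is.na(df$onset_override)] <- "none"
  curation_table(df$variant_key, df$acmg_class, df$onset_override)
}

#' @rdname read_curation_table
#' @param curation A curation table.
#' @export
write_curation_table <- function(curation, path) {
  .write_tsv(curation, path)
}

#' Write a six-column PED file for trio genotype work
#'
#' Emits the classical PED layout (family, individual, father, mother, sex,
#' phenotype) with one trio per proband: the extended pedigree cannot be
#' expressed in PED and is exchanged through the family TSV instead.
#'
#' @param probands A proband table.
#' @param path Output file.
#' @return `path`, invisibly.
#' @export
write_trio_ped <- function(probands, path) {
  probands <- validate_probands(probands)
  sex_code <- ifelse(probands$sex == "male", 1L, 2L)
  lines <- c(
    paste(probands$family_id, paste0(probands$patient_id, "_fa"),
          0L, 0L, 1L, 1L, sep = "\t"),
    paste(probands$family_id, paste0(probands$patient_id, "_mo"),
          0L, 0L, 2L, 1L, sep = "\t"),
    paste(probands$family_id, probands$patient_id,
          paste0(probands$patient_id, "_fa"),
          paste0(probands$patient_id, "_mo"),
          sex_code, 2L, sep = "\t"))
  writeLines(lines, path)
  invisible(path)
}
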