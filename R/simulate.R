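# Synthetic cohort generation.
#
# Generation is latent-tier-first: each proband is assigned a latent
# suspicion tier, then variants, chromosomal events, flags and pedigrees
# consistent with that tier are emitted. Because the generator and the
# triage filter share the same TriageConfig, every variant destined to be a
# PV passes triage, which makes tier-prevalence recovery by the full
# pipeline a well-posed test.

#' Simulation configuration
#'
#' Defaults emulate a nationwide consecutive pediatric cohort of 198
#' patients: diagnosis mix 53.0% hematologic / 22.2% CNS / 25.0% solid;
#' age bands 0-5 / 6-10 / 11-15 / 16-17 at 52.5/20.7/19.7/7.0%; 61.1%
#' male; prevalence 10.6% childhood-onset CPS, 4.5% adult-onset CPS,
#' 11.6% heterozygous carriers of biallelic-CPS-gene PVs. The background
#' relative-cancer hazard is piecewise constant in the age bands 0-17 /
#' 18-45 / 46+ and is calibrated so that about 96% of families have at
#' least one cancer event.
#'
#' @param n_patients Cohort size.
#' @param diagnosis_mix Named proportions (hematologic, CNS, solid);
#'   must sum to 1.
#' @param age_mix Proportions of the four age bands; must sum to 1.
#' @param male_fraction Proportion of male probands.
#' @param childhood_cps_prevalence,adult_cps_prevalence,biallelic_carrier_prevalence,criteria_only_prevalence
#'   Latent tier prevalences; their sum must be <= 1.
#' @param trisomy21_fraction Fraction of childhood-onset CPS due to
#'   trisomy 21 rather than a sequence PV.
#' @param hazard Named per-year background cancer hazards for relative age
#'   bands 0-17, 18-45 and 46+.
#' @param n_siblings_mean,n_parent_siblings_mean,n_cousins_mean Mean counts
#'   for Poisson-distributed pedigree sizes (parents and grandparents are
#'   always present; great-grandparents appear with probability 0.3 each).
#' @param verification_mix Named probabilities for the verification status
#'   of relative cancer events.
#' @param depth_mean Mean sequencing depth of emitted calls.
#' @param decoy_rate Mean number of decoy (non-PV) calls per patient.
#' @param triage A [triage_config()] shared with the filter cascade.
#' @return A list of class `simulation_config`.
#' @export
simulation_config <- function(n_patients = 198,
                              diagnosis_mix = c(hematologic = 0.530,
                                                CNS = 0.222, solid = 0.248),
                              age_mix = c(0.525, 0.207, 0.197, 0.071),
                              male_fraction = 0.611,
                              childhood_cps_prevalence = 0.106,
                              adult_cps_prevalence = 0.045,
                              biallelic_carrier_prevalence = 0.116,
                              criteria_only_prevalence = 0.212,
                              trisomy21_fraction = 0.19,
                              hazard = c(child = 2e-4, young = 3e-3,
                                         old = 2.6e-2),
                              n_siblings_mean = 1.2,
                              n_parent_siblings_mean = 3,
                              n_cousins_mean = 3,
                              verification_mix = c(verified = 0.55,
                                                   unverifiable = 0.25,
                                                   abroad = 0.08,
                                                   declined_consent = 0.07,
                                                   reported_only = 0.05),
                              depth_mean = 30,
                              decoy_rate = 3,
                              triage = triage_config()) {
  prev <- c(childhood_cps_prevalence, adult_cps_prevalence,
            biallelic_carrier_prevalence, criteria_only_prevalence)
  if (any(prev < 0 | prev > 1)) stop("prevalences must lie in [0, 1]")
  if (sum(prev) > 1) stop("tier prevalences must sum to at most 1")
  if (abs(sum(diagnosis_mix) - 1) > 1e-9) stop("diagnosis_mix must sum to 1")
  if (abs(sum(age_mix) - 1) > 1e-9) stop("age_mix must sum to 1")
  structure(list(n_patients = n_patients, diagnosis_mix = diagnosis_mix,
                 age_mix = age_mix, male_fraction = male_fraction,
                 childhood_cps_prevalence = childhood_cps_prevalence,
                 adult_cps_prevalence = adult_cps_prevalence,
                 biallelic_carrier_prevalence = biallelic_carrier_prevalence,
                 criteria_only_prevalence = criteria_only_prevalence,
                 trisomy21_fraction = trisomy21_fraction,
                 hazard = hazard,
                 n_siblings_mean = n_siblings_mean,
                 n_parent_siblings_mean = n_parent_siblings_mean,
                 n_cousins_mean = n_cousins_mean,
                 verification_mix = verification_mix,
                 depth_mean = depth_mean, decoy_rate = decoy_rate,
                 triage = triage),
            class = "simulation_config")
}

.sim_diagnoses <- list(
  hematologic = c("precursor B-ALL", "lymphoma", "acute myeloid leukemia",
                  "precursor T-ALL", "Langerhans cell histiocytosis",
                  "myelodysplastic syndrome"),
  CNS = c("low-grade glioma", "high-grade glioma", "ependymoma",
          "medulloblastoma", "pilocytic astrocytoma"),
  solid = c("Wilms tumor", "neuroblastoma", "rhabdomyosarcoma",
            "osteosarcoma", "Ewing's sarcoma", "yolk sac tumor"))

.relative_cancers <- c("breast cancer", "colon cancer", "lung cancer",
                       "prostate cancer", "melanoma", "lymphoma",
                       "kidney cancer", "glioblastoma", "ovarian cancer",
                       "gastric cancer")
.relative_cancer_w <- c(0.15, 0.14, 0.16, 0.10, 0.10, 0.06,
                        0.04, 0.03, 0.06, 0.16)

# deterministic 31-bit string hash, used to derive per-family RNG substreams
# so pedigree generation is independent of family order
.stable_hash <- function(x) {
  b <- utf8ToInt(x)
  h <- 0
  for (v in b) h <- (h * 31 + v) %% 2147483647
  as.integer(h)
}

cumulative_hazard <- function(age, hazard) {
  pmin(age, 17) * hazard[["child"]] +
    pmax(pmin(age, 45) - 17, 0) * hazard[["young"]] +
    pmax(age - 45, 0) * hazard[["old"]]
}

# inverse of the piecewise-linear cumulative hazard
invert_hazard <- function(H, hazard) {
  H17 <- 17 * hazard[["child"]]
  H45 <- H17 + 28 * hazard[["young"]]
  ifelse(H <= H17, H / hazard[["child"]],
         ifelse(H <= H45, 17 + (H - H17) / hazard[["young"]],
                45 + (H - H45) / hazard[["old"]]))
}

#' Generate a three-generation pedigree for one proband
#'
#' Relatives receive current ages consistent with their generation; cancer
#' events are drawn from the age-band background hazard, dated by inverting
#' the cumulative hazard, and given a verification status from the
#' configured mix.
#'
#' @param proband One row of a proband table.
#' @param config A [simulation_config()].
#' @return A family table for the proband's family.
#' @export
generate_pedigree <- function(proband, config = simulation_config()) {
  fid <- proband$family_id
  page <- proband$age_at_diagnosis
  rel <- list()
  add <- function(id, relation, lineage, age) {
    rel[[length(rel) + 1]] <<- list(id = id, relation = relation,
                                    lineage = lineage, age = age)
  }
  mo_age <- page + 18 + stats::rpois(1, 13)
  fa_age <- page + 18 + stats::rpois(1, 15)
  add("mo", "mother", "not_applicable", mo_age)
  add("fa", "father", "not_applicable", fa_age)
  n_sib <- stats::rpois(1, config$n_siblings_mean)
  for (s in seq_len(n_sib)) {
    add(paste0("sib", s), "sibling", "not_applicable",
        max(0, page + sample(-10:10, 1)))
  }
  for (side in c("maternal", "paternal")) {
    base <- if (side == "maternal") mo_age else fa_age
    add(paste0(side, "_gm"), "grandparent", side, base + 20 + stats::rpois(1, 8))
    add(paste0(side, "_gf"), "grandparent", side, base + 22 + stats::rpois(1, 8))
    n_ps <- stats::rpois(1, config$n_parent_siblings_mean / 2)
    for (s in seq_len(n_ps)) {
      add(paste0(side, "_ps", s), "parent_sibling", side,
          max(18, base + sample(-8:8, 1)))
    }
    n_cz <- stats::rpois(1, config$n_cousins_mean / 2)
    for (s in seq_len(n_cz)) {
      add(paste0(side, "_cz", s), "cousin", side,
          max(0, page + sample(-12:12, 1)))
    }
    if (stats::runif(1) < 0.3) {
      add(paste0(side, "_ggm"), "great_grandparent", side,
          base + 42 + stats::rpois(1, 8))
    }
  }

  rows <- lapply(rel, function(r) {
    H <- cumulative_hazard(r$age, config$hazard)
    p_event <- 1 - exp(-H)
    if (stats::runif(1) < p_event) {
      u <- stats::runif(1, 0, p_event)
      age_dx <- floor(invert_hazard(-log(1 - u), config$hazard))
      ver <- sample(names(config$verification_mix), 1,
                    prob = config$verification_mix)
      family_table(fid, paste0(fid, "_", r$id), r$relation, r$lineage,
                   diagnosis = sample(.relative_cancers, 1,
                                      prob = .relative_cancer_w),
                   age_at_diagnosis = age_dx,
                   known_at_proband_diagnosis = stats::runif(1) < 0.95,
                   verification = ver)
    } else {
      family_table(fid, paste0(fid, "_", r$id), r$relation, r$lineage)
    }
  })
  do.call(rbind, rows)
}

#' Trio genotypes consistent with a parental origin
#'
#' @param inheritance `"maternal"`, `"paternal"` or `"de_novo"`.
#' @return Named character vector (child, mother, father) of genotypes.
#' @export
#' @examples
#' generate_trio_genotypes("de_novo")
generate_trio_genotypes <- function(inheritance) {
  stopifnot(inheritance %in% c("maternal", "paternal", "de_novo"))
  c(child = "het",
    mother = if (inheritance == "maternal") "het" else "ref",
    father = if (inheritance == "paternal") "het" else "ref")
}

.sim_pv_quality <- function(n, config) {
  tri <- config$triage
  # truncated draws guarantee that emitted PVs clear the QC thresholds
  depth <- tri$min_depth + stats::rpois(n, config$depth_mean - tri$min_depth)
  gq <- pmin(99, tri$min_gq + stats::rpois(n, 40))
  lo <- stats::pbeta(tri$min_vaf, 30, 30)
  vaf <- round(stats::qbeta(stats::runif(n, lo, 1), 30, 30), 3)
  list(depth = depth, gq = gq, vaf = vaf)
}

.sim_variant <- function(pid, gene, chrom, onto_class, config, n = 1) {
  q <- .sim_pv_quality(n, config)
  cons <- sample(c("stop_gained", "frameshift_variant", "missense_variant",
                   "splice_donor_variant"), n, replace = TRUE,
                 prob = c(0.25, 0.3, 0.35, 0.1))
  deltas <- ifelse(cons == "splice_donor_variant",
                   "-0.32,-0.28,-0.41,-0.05", "")
  af <- ifelse(stats::runif(n) < 0.7, NA_real_,
               round(stats::runif(n, 0, config$triage$max_af * 0.9), 5))
  variant_table(patient_id = pid, chrom = chrom,
                pos = sample.int(2e8, n), ref = "A", alt = "T",
                genotype = "het", depth = q$depth, gq = q$gq, vaf = q$vaf,
                gene = gene, consequence = cons, gnomad_max_af = af,
                cadd_phred = round(pmax(15, stats::rnorm(n, 30, 5)), 1),
                splice_deltas = deltas,
                acmg_class = onto_class,
                inheritance = sample(c("maternal", "paternal", "de_novo",
                                       "unknown"), n, replace = TRUE,
                                     prob = c(0.35, 0.35, 0.1, 0.2)))
}

.sim_decoys <- function(pid, config) {
  n <- stats::rpois(1, config$decoy_rate)
  if (n == 0) return(NULL)
  kind <- sample(c("low_depth", "low_gq", "low_vaf", "intronic", "utr",
                   "high_af", "off_panel", "vus", "benign"), n,
                 replace = TRUE)
  tri <- config$triage
  q <- .sim_pv_quality(n, config)
  v <- variant_table(patient_id = rep(pid, n), chrom = "7",
                     pos = sample.int(2e8, n), ref = "G", alt = "C",
                     depth = q$depth, gq = q$gq, vaf = q$vaf,
                     gene = "TP53", consequence = "missense_variant",
                     gnomad_max_af = 0.001,
                     cadd_phred = round(stats::runif(n, 1, 35), 1),
                     acmg_class = 3L)
  v$depth[kind == "low_depth"] <- tri$min_depth - 1
  v$gq[kind == "low_gq"] <- tri$min_gq - 1
  v$vaf[kind == "low_vaf"] <- round(tri$min_vaf / 2, 3)
  v$consequence[kind == "intronic"] <- "intron_variant"
  v$consequence[kind == "utr"] <- "3_prime_UTR_variant"
  v$gnomad_max_af[kind == "high_af"] <- round(tri$max_af * 5, 4)
  v$gene[kind == "off_panel"] <- "DECOYGENE"
  v$cadd_phred[kind == "vus"] <- round(stats::runif(sum(kind == "vus"),
                                                    21, 35), 1)
  v$acmg_class[kind == "benign"] <- 2L
  validate_variants(v)
}

#' Generate a synthetic cohort bundle
#'
#' Deterministic given `(config, seed)`. Probands are drawn from the
#' configured demographic mixes, assigned a latent tier, and given
#' variants, chromosomal events, clinical flags and pedigrees consistent
#' with that tier. Pedigrees use per-family RNG substreams derived by a
#' stable hash of the family id, so they do not depend on generation
#' order.
#'
#' @param config A [simulation_config()].
#' @param seed Integer seed.
#' @return A list of class `cps_cohort` with elements `probands`,
#'   `relatives`, `variants`, `curation` and `manifest`.
#' @export
generate_cohort <- function(config = simulation_config(), seed = 1L) {
  stopifnot(inherits(config, "simulation_config"))
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
  set.seed(seed)

  n <- config$n_patients
  pid <- sprintf("S%03d", seq_len(n))
  sex <- ifelse(stats::runif(n) < config$male_fraction, "male", "female")
  band <- sample(4, n, replace = TRUE, prob = config$age_mix)
  age <- c(sample(0:5, n, TRUE), sample(6:10, n, TRUE),
           sample(11:15, n, TRUE), sample(16:17, n, TRUE))[
             seq_len(n) + (band - 1) * n]
  dgrp <- sample(names(config$diagnosis_mix), n, replace = TRUE,
                 prob = config$diagnosis_mix)
  diagnosis <- vapply(dgrp, function(g) sample(.sim_diagnoses[[g]], 1),
                      character(1))

  tier_p <- c(childhood = config$childhood_cps_prevalence,
              adult = config$adult_cps_prevalence,
              carrier = config$biallelic_carrier_prevalence,
              criteria = config$criteria_only_prevalence)
  tier <- sample(c(names(tier_p), "background"), n, replace = TRUE,
                 prob = c(tier_p, 1 - sum(tier_p)))

  panel <- default_panel()
  child_mono <- panel$symbol[panel$in_cancer314 &
                               panel$inheritance_mode == "monoallelic" &
                               panel$onset_default == "childhood"]
  adult_mono <- panel$symbol[panel$in_cancer314 &
                               panel$inheritance_mode == "monoallelic" &
                               panel$onset_default == "adult"]
  biall <- panel$symbol[panel$in_cancer314 &
                          panel$inheritance_mode == "biallelic" &
                          panel$onset_default == "childhood"]

  tumor_flags <- rep("", n)
  chrom_events <- rep("", n)
  variants <- list()
  for (i in seq_len(n)) {
    if (tier[i] == "childhood") {
      if (stats::runif(1) < config$trisomy21_fraction) {
        chrom_events[i] <- "trisomy_21"
      } else {
        variants[[length(variants) + 1]] <-
          .sim_variant(pid[i], sample(child_mono, 1), "17",
                       sample(4:5, 1), config)
      }
    } else if (tier[i] == "adult") {
      variants[[length(variants) + 1]] <-
        .sim_variant(pid[i], sample(adult_mono, 1), "13",
                     sample(4:5, 1), config)
    } else if (tier[i] == "carrier") {
      variants[[length(variants) + 1]] <-
        .sim_variant(pid[i], sample(biall, 1), "16", sample(4:5, 1), config)
    } else if (tier[i] == "criteria") {
      tumor_flags[i] <- "multiple_primaries"
    }
    d <- .sim_decoys(pid[i], config)
    if (!is.null(d)) variants[[length(variants) + 1]] <- d
  }
  variants <- if (length(variants)) do.call(rbind, variants) else
    variant_table(character(0), character(0), integer(0), character(0),
                  character(0))

  probands <- proband_table(pid, sex, age, diagnosis,
                            tumor_flags = tumor_flags,
                            chromosomal_events = chrom_events,
                            feedback_level = sample(1:3, n, replace = TRUE,
                                                    prob = c(0.096, 0.121,
                                                             0.783)))

  relatives <- do.call(rbind, lapply(seq_len(n), function(i) {
    sub_seed <- (.stable_hash(probands$family_id[i]) + seed) %% 2147483647
    local_rng(sub_seed, generate_pedigree(probands[i, , drop = FALSE],
                                          config))
  }))

  structure(list(probands = probands, relatives = relatives,
                 variants = variants, curation = curation_table(),
                 manifest = list(seed = seed, config = config,
                                 latent_tier = stats::setNames(tier, pid))),
            class = "cps_cohort")
}

# evaluate expr under a temporary RNG state
local_rng <- function(seed, expr) {
  old <- get(".Random.seed", globalenv())
  on.exit(assign(".Random.seed", old, globalenv()))
  set.seed(seed)
  expr
}

#' @export
print.cps_cohort <- function(x, ...) {
  cat("Synthetic CPS screening cohort\n")
  cat("  probands: ", nrow(x$probands), "\n", sep = "")
  cat("  relatives:", nrow(x$relatives), "\n")
  cat("  variant calls:", nrow(x$variants), "\n")
  if (!is.null(x$manifest$seed)) cat("  seed:", x$manifest$seed, "\n")
  invisible(x)
}

#' Write a cohort bundle to a directory
#'
#' Emits the interchange formats (annotated VCF, family TSV, proband TSV,
#' curation TSV, trio PED) plus a JSON manifest with the generating seed.
#'
#' @param cohort A `cps_cohort` bundle.
#' @param dir Output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_cohort <- function(cohort, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  write_annotated_vcf(cohort$variants, file.path(dir, "variants.vcf"))
  write_family_table(cohort$relatives, file.path(dir, "families.tsv"))
  write_proband_table(cohort$probands, file.path(dir, "probands.tsv"))
  write_curation_table(cohort$curation, file.path(dir, "curation.tsv"))
  write_trio_ped(cohort$probands, file.path(dir, "trios.ped"))
  manifest <- list(seed = cohort$manifest$seed,
                   n_patients = nrow(cohort$probands))
  jsonlite::write_json(manifest, file.path(dir, "manifest.json"),
                       auto_unbox = TRUE)
  invisible(dir)
}
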