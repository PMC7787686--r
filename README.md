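# cpsscreen

Systematic germline screening of pediatric cancer cohorts for cancer
predisposition syndromes (CPS).

About one child in ten with cancer carries a germline pathogenic variant
(PV) in a cancer predisposition gene, and clinical checklists exist to
decide who should be referred for genetic evaluation. `cpsscreen`
implements, as a tested and reusable R pipeline, the full decision chain a
nationwide screening program applies to every enrolled child:

1. **Variant triage.** Annotated germline calls are filtered by call
   quality (read depth ≥ 8, genotype quality ≥ 20, variant allele fraction
   ≥ 0.2), Sequence Ontology consequence (intronic, intergenic and 3'/5'
   UTR calls are excluded), membership in a screening panel of 314 cancer
   genes and 59 ACMG actionable genes, and population frequency (maximum
   allele frequency < 1% in any large gnomAD population, with a separate
   threshold for high-carrier-frequency genes such as *ATM* and *CHEK2*).
   Retained calls are designated PVs (curated ACMG class 4/5) or
   shortlisted VUS (class 3, CADD-PHRED > 20). A splice effect is called
   significant when at least three prediction programs lose ≥ 10% of their
   score or a strong cryptic splice site is generated. Every excluded call
   carries a machine-readable reason code.
2. **Suspicion-tier classification.** Each patient is counted once, at the
   top-most applicable tier:
   `confirmed childhood-onset CPS > confirmed adult-onset CPS >
   biallelic-gene carrier > clinical criteria only > family history only >
   none`. Childhood-onset confirmation requires a childhood-onset PV
   consistent with the gene's inheritance mode (or a qualifying
   chromosomal event: trisomy 21, UPD 11p); a single heterozygous PV in a
   recessive CPS gene makes a carrier, not a patient with CPS. Trio
   genotypes resolve parental origin (maternal / paternal / de novo) and
   compound-heterozygote phase.
3. **Clinical-criteria rule engines.** Jongmans' criteria 1–5 and the
   MIPOGG universal/direct-referral rules are evaluated per patient over a
   three-generation pedigree, with per-criterion audit booleans. Family
   events count only when they were known at the proband's diagnosis.
4. **Cohort statistics.** Tier counts and fractions, group-level criteria
   fulfillment, family-history concordance and verification accounting,
   Pearson chi-square comparisons, and feedback-level disclosure filtering
   (ACMG-actionable-only, + cancer panel, + all findings; heterozygous
   findings in solely recessive genes are withheld unless familial testing
   is warranted).

A synthetic-cohort generator (`generate_cohort()`) emits probands,
pedigrees, annotated variants and trio genotypes with configurable tier
prevalences, so that every stage of the pipeline is testable without
patient data; `study_cohort()` rebuilds the published 198-patient study
cohort from its printed per-patient tables.

## Worked example

```r
library(cpsscreen)

pp <- study_pipeline()   # encoded study cohort through the full pipeline
pp$summary
#> CPS screening cohort summary (n = 198)
#> Suspicion triangle (each patient counted once, top-most tier):
#>   confirmed_childhood     21 (10.6%)
#>   confirmed_adult          8 (4.0%)
#>   biallelic_carrier       23 (11.6%)
#>   criteria_only           42 (21.2%)
#>   family_history_only      0 (0.0%)
#>   none                   104 (52.5%)
#> Confirmed CPS: 29 (14.6%); multi-PV carriers: 7 (3.5%)
#> Any biallelic-CPS-gene PV: 27 (13.6%)
#> Criteria: Jongmans 56, MIPOGG 64, either 70 (35.4%)
#> Jongmans among childhood-onset CPS: 17/21 (81.0%)
#> Jongmans among adult-onset CPS:     2/9 (22.2%)
```

Of 198 patients, 29 (14.6%) have a confirmed CPS — 21 childhood-onset
(one patient carries both a childhood- and an adult-onset PV and is
counted once, in the childhood tier) and 8 counted as adult-onset — a
further 23 (11.6%) are heterozygous carriers of PVs in recessive CPS
genes, and 42 fulfill referral criteria without any PV. Jongmans'
criteria flag most childhood-onset CPS patients (17/21) but few
adult-onset ones (2/9); the difference is the cohort's headline contrast:

```r
pearson_chi2(matrix(c(2, 17, 7, 4), 2))
#> Pearson chi-square (no correction)
#>   X-squared = 9.357, df = 1, p = 0.002221
```

Synthetic cohorts work the same way:

```r
co <- generate_cohort(simulation_config(), seed = 42)
run_pipeline(co)$summary
```

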