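---
title: "Methods: germline CPS screening of pediatric cancer cohorts"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: germline CPS screening of pediatric cancer cohorts}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(cpsscreen)
```

## The screening model

`cpsscreen` models the decision chain of a population-based germline
screening program for cancer predisposition syndromes (CPS) in children
(0–17 years at diagnosis). The unit of analysis is the proband; the
evidence is (i) curated annotated germline variant calls, (ii) the
child's diagnosis, phenotype checklist and chromosomal events, and
(iii) a three-generation pedigree with dated, verification-tagged cancer
events. The output is a single suspicion tier per patient plus a full
audit trail.

The tier scheme is a strict precedence order; each patient is counted
once, at the top-most level they qualify for:

1. **confirmed childhood-onset CPS** — a childhood-onset pathogenic
   variant (PV, curated ACMG class 4/5) consistent with the gene's
   inheritance mode, or a qualifying chromosomal event (trisomy 21,
   paternal UPD 11p);
2. **confirmed adult-onset CPS** — an adult-onset PV in a
   monoallelic-mode gene;
3. **biallelic-gene carrier** — only heterozygous PVs in recessive CPS
   genes;
4. **criteria only** — Jongmans' criteria or MIPOGG fulfilled without a
   PV;
5. **family history only**; 6. **none**.

Because the precedence is total, tier counts always partition the cohort
— an invariant the test suite checks on every generated cohort.

## Variant triage

All thresholds live in one `triage_config()` object shared by the filter
cascade and the synthetic generator:

| parameter | default | meaning |
|---|---|---|
| `min_depth` | 8 reads | minimum read depth (inclusive) |
| `min_gq` | 20 | minimum genotype quality (inclusive) |
| `min_vaf` | 0.2 | minimum variant allele fraction (inclusive) |
| `max_af` | 0.01 | maximum population AF (strict `<`) |
| `max_af_high_freq_genes` | 0.05 | alternate AF cut-off for high-carrier-frequency genes |
| `cadd_vus_threshold` | 20 | CADD-PHRED bound for VUS shortlisting (strict `>`) |
| `splice_reduction_fraction` | 0.10 | per-program score loss counting as a splice hit |
| `splice_min_programs` | 3 | programs that must lose score |

Boundary semantics follow the stated rules: the quality thresholds are
inclusive (`depth = 8` passes), the frequency and CADD thresholds are
strict (`AF = 0.01` and `CADD = 20.0` fail). Missing annotation is
handled asymmetrically, and deliberately so: a missing quality field
fails (the call is not trusted), while a missing population frequency
passes (the variant has simply never been observed — novel variants must
survive). The alternate frequency threshold for genes such as *ATM* and
*CHEK2* is not published; 5% is the package default and is
config-exposed.

The cascade order (quality → consequence → panel → frequency →
classification) is fixed so that reason codes are stable; the retained
*set* is order-independent, which the tests verify against a brute-force
conjunction of the individual predicates. Curated chromosomal-event
records (trisomy 21 carried as symbolic calls) and curated CNVs enter
pre-annotated and bypass the sequence-level filters that do not apply to
them. A "strong cryptic splice site" is accepted as a boolean annotation
input: no quantitative definition is available to recompute it.

## Clinical-criteria rule engines

**Jongmans' criteria.** Criteria 1–5 are implemented as audit booleans
whose disjunction is the fulfillment flag. Criterion 6 (excessive
treatment toxicity) is deliberately excluded from the rule set: it has
no operational definition. Design choices that needed fixing:

* Family events count toward criteria only when they were **known at the
  proband's diagnosis** and are malignant; a benign tumor in a relative
  is recorded but never counted.
* "Two or more malignancies in family members < 18" counts *events*,
  not relatives.
* Same-lineage counting ("2+ 1st/2nd-degree relatives in the same
  parental lineage with cancer < 45") counts distinct relatives; the
  father and mother anchor their own lineage, siblings pool with
  neither, and maternal and paternal sides are never pooled.

**MIPOGG.** The universal anamnestic criteria (multiple primaries,
bilateral/multifocal tumors, dysmorphic features *deemed related to
cancer predisposition* — a stronger requirement than Jongmans'
phenotype criterion, which any checklist finding satisfies), the family
criteria over *close* relatives, and the direct-referral tumor list.
"Close relative" is taken as degree ≤ 2 and is config-exposed;
half-siblings are degree 2 for degree-based rules but are explicitly
included in the "parent/sibling/half-sibling < 50" clause. The
indicative-neoplasm and direct-referral lists are packaged exactly as
printed (they are marked as examples in the source checklist, so they
are extendable via function arguments).

Both engines are order-independent in the relatives list and monotone in
qualifying evidence; the audit-completeness invariant
(`fulfilled == OR(components)`) is tested exhaustively over all 2^8
component combinations per rule set, using input fragments that each
activate exactly one component.

## Zygosity, phase and multi-PV counting

Within one gene, two heterozygous PVs with opposite parental origins are
`biallelic_confirmed_trans`; two without trio evidence are
`biallelic_phase_unknown`. A phase-unknown pair in a recessive
childhood-onset gene **does** confirm childhood CPS, with an explicit
caveat flag: this mirrors how trio data resolved the one biallelic case
in the study cohort while keeping non-trio behavior defined rather than
silently optimistic. A patient carrying both childhood- and adult-onset
PVs is counted once, in the childhood tier, but still belongs to the
denominator of the adult-PV carrier group; their criteria fulfillment is
attributed to the childhood syndrome and does not count toward the
adult group's fulfillment — this is exactly the counting convention
needed to reproduce the published group percentages (17/21 and 2/9).
Multi-PV detection counts PVs plus chromosomal events, with trisomy 21
counted once however it was recorded.

## The encoded study cohort

`study_cohort()` rebuilds the 198-patient cohort from the printed
per-patient tables: 21 childhood-onset CPS patients, 9 adult-onset-PV
carriers (one shared with the childhood tier), 23 additional
biallelic-gene carriers, six patients with ACMG actionable secondary
findings outside CPS genes, and 140 filler patients reproducing the
printed marginals (42 criteria-fulfilled without a PV; feedback levels
19/24/155). Where a patient's printed criteria outcome cannot be derived
from printed inputs (three CPS patients and seven carriers), the outcome
is stored as a *recorded* value and flagged as such in the audit table;
everything else is computed from encoded diagnoses, phenotypes and
pedigrees. The packaged gene panel is a synthetic stand-in with the
published cardinality (314 + 59) and correct attributes for every gene
named in the findings tables; filler symbols are clearly synthetic
(`CPG001`…).

Known source inconsistencies are encoded, not resolved: the biallelic
table lists 28 rows over 27 distinct patients (four of whom also carry a
monoallelic PV, so the carrier *tier* holds 23); the family-history text
gives 96.5% against the table's 95.5% (the fixtures follow the
tables); and the headline p-value (0.0022) matches the Jongmans-only
17/21-versus-2/9 comparison, which is the table the package reproduces.
One patient's tumor was re-diagnosed after sequencing; the criteria are
evaluated against the diagnosis as known at evaluation time (synovial
sarcoma), which reproduces the printed negative outcome.

## The synthetic generator

`generate_cohort()` is latent-tier-first: each proband draws a latent
tier (defaults 10.6% childhood CPS, 4.5% adult CPS, 11.6% carrier,
21.2% criteria-only), then evidence consistent with that tier — a PV
drawn to pass the shared `triage_config()` (truncated depth/GQ/VAF
distributions around 30×/high/0.5), trisomy 21 for a configurable share
of childhood cases, decoy variants that each fail exactly one filter,
and a three-generation pedigree. This makes prevalence recovery a
well-posed test: the acceptance suite checks that 95% Clopper–Pearson
intervals from the full pipeline cover the generating prevalences in at
least 93 of 100 seeded replicates at n = 198.

Background relative cancers use a piecewise-constant hazard in the age
bands 0–17 / 18–45 / 46+ (defaults 2·10⁻⁴, 3·10⁻³, 2.6·10⁻² per
relative-year): the clinical criteria only test the age cut-offs 18, 45
and 50, so band-level fidelity suffices. The old-age rate is calibrated
so that ≈96% of families have at least one cancer event, matching the
study's family-history burden. Event ages are drawn by inverting the
cumulative hazard, and per-family RNG substreams are derived by a stable
hash of the family id, so pedigrees do not depend on generation order.
Relative counts per family (Poisson siblings/aunts/uncles/cousins,
grandparents always present) are plausible defaults, config-exposed and
not claimed to be faithful to any cohort.

What the generator does **not** emulate — and what passing tests
therefore do not show about real data: genome-wide variant burden (only
panel-relevant calls plus decoys are emitted), linkage and haplotype
structure, mosaicism, recall bias in family histories, and correlation
between diagnosis and latent tier (tiers are drawn independently of the
diagnosis mix).

## Numerical choices

* Percentages render to one decimal, rounding half away from zero.
* `pearson_chi2()` defaults to no continuity correction — the published
  headline p-value (0.0022) is the uncorrected statistic on
  `[[2,7],[17,4]]`; Yates correction is config-exposed. The test suite
  cross-checks the statistic against a from-first-principles computation
  and the p-value against a 200,000-resample permutation null under
  fixed margins, comparing the asymptotic p with the permutation mid-p
  (the quantity the chi-square approximation targets for a discrete
  null) within three Monte-Carlo standard errors plus an allowance for
  the asymptotic approximation error at n ≤ 60.
* Degenerate inputs are explicit: zero-margin contingency tables error;
  a verification denominator of zero returns an `NA` fraction; a child
  reference genotype makes inheritance assignment an error, and a
  missing parent makes it `unknown`.
* Test and acceptance problem sizes: 100 seeded cohorts of n = 198 for
  the recovery/partition properties, 40 seeds for the binomial check on
  latent childhood counts, three cohorts (~594 families) for the
  pedigree event-rate band, 2×10⁵ permutation resamples per table.

## Limitations

The package classifies from *curated* inputs: it does not call variants,
compute CADD or splice scores, or automate ACMG classification — those
enter as annotations, and the curation table always wins over the VCF
class. The packaged criteria lists cover exactly the printed terms;
real MIPOGG tumor-specific cascades are broader. Oligogenic
pathogenicity prediction is out of scope; patients with several PVs are
flagged (`multi_pv`), nothing more. Disclosure filtering implements the
three feedback levels and recessive-carrier withholding as stated rules,
not as a model of genetic-counselling practice.
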