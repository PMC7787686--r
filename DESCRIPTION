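Package: cpsscreen
Title: Germline Cancer Predisposition Screening for Pediatric Cancer Cohorts
Version: 0.1.0
Authors@R: person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: A tested re-implementation of a nationwide germline screening
    workflow for cancer predisposition syndromes (CPS) in pediatric cancer
    patients. Provides variant triage with explicit quality, consequence,
    population-frequency and splice-effect thresholds; assignment of patients
    to a tiered suspicion scheme (childhood-onset CPS, adult-onset CPS,
    biallelic-gene carrier, clinical-criteria only, family history only);
    rule engines for Jongmans' criteria and the McGill Interactive Pediatric
    OncoGenetic Guidelines (MIPOGG) over three-generation pedigrees;
    relationship-degree computation and family-history concordance and
    verification accounting; cohort summaries with Pearson chi-square
    comparisons and feedback-level disclosure filtering; and a synthetic
    cohort generator so that every stage is testable without patient data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    jsonlite,
    yaml,
    vcfR
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
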