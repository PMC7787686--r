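# The triage filter cascade.

test_that("call-quality thresholds are inclusive and missing values fail", {
  cases <- data.frame(depth = c(8, 7, 30, 8, NA),
                      gq = c(20, 99, 20, 20, 99),
                      vaf = c(0.20, 0.50, 0.19, 0.20, 0.5),
                      pass = c(TRUE, FALSE, FALSE, TRUE, FALSE))
  v <- do.call(rbind, lapply(seq_len(nrow(cases)), function(i) {
    x <- good_variant(pos = i)
    x$depth <- cases$depth[i]; x$gq <- cases$gq[i]; x$vaf <- cases$vaf[i]
    x
  }))
  expect_equal(passes_call_quality(v), cases$pass)
})

test_that("consequence filter drops intronic/intergenic/UTR, keeps splice", {
  csq <- c("intron_variant", "intergenic_variant", "3_prime_UTR_variant",
           "5_prime_UTR_variant", "missense_variant", "splice_donor_variant",
           "splice_acceptor_variant", "stop_gained")
  v <- do.call(rbind, lapply(seq_along(csq), function(i) {
    x <- good_variant(pos = i); x$consequence <- csq[i]; x
  }))
  expect_equal(passes_consequence_filter(v),
               c(FALSE, FALSE, FALSE, FALSE, TRUE, TRUE, TRUE, TRUE))
})

test_that("frequency filter is strict at 1% with a per-gene alternate", {
  panel <- tiny_panel()
  v <- rbind(good_variant(gene = "RB1", pos = 1L),
             good_variant(gene = "RB1", pos = 2L),
             good_variant(gene = "CHEK2", pos = 3L),
             good_variant(gene = "CHEK2", pos = 4L),
             good_variant(gene = "RB1", pos = 5L))
  v$gnomad_max_af <- c(0.009, 0.01, 0.012, 0.05, NA)
  expect_equal(passes_frequency_filter(v, panel),
               c(TRUE, FALSE, TRUE, FALSE, TRUE))
})

test_that("splice significance needs three reduced programs or a cryptic site", {
  expect_true(evaluate_splice_effect(c(-0.12, -0.15, -0.11, -0.02), FALSE))
  expect_false(evaluate_splice_effect(c(-0.12, -0.15, -0.05, -0.02), FALSE))
  expect_true(evaluate_splice_effect(c(0, 0, 0, 0), TRUE))
  # exactly -0.10 counts as a 10% reduction
  expect_true(evaluate_splice_effect(c(-0.10, -0.10, -0.10), FALSE))
  expect_warning(res <- evaluate_splice_effect(c(-0.5, -0.4), FALSE),
                 "insufficient")
  expect_false(res)
})

test_that("VUS shortlisting takes class 3 with CADD strictly above 20", {
  v <- rbind(good_variant(pos = 1L, acmg_class = 3L),
             good_variant(pos = 2L, acmg_class = 3L),
             good_variant(pos = 3L, acmg_class = 5L))
  v$cadd_phred <- c(21, 20.0, 35)
  v$gnomad_max_af <- c(0.005, 0.005, 0)
  expect_equal(shortlist_vus(v), c(TRUE, FALSE, FALSE))
})

test_that("the cascade excludes each decoy with its first failing reason", {
  d <- decoy_variants()
  tri <- run_triage(d[setdiff(names(d), "expected_reason")], tiny_panel())
  expect_true(all(tri$status == "excluded"))
  expect_equal(tri$failed_filters, d$expected_reason)
  # retained rows carry no reasons; excluded rows exactly one
  good <- run_triage(good_variant(), tiny_panel())
  expect_equal(good$status, "pv")
  expect_equal(good$failed_filters, "")
})

test_that("curation overrides the class carried in the VCF", {
  v <- good_variant(acmg_class = 3L)
  cur <- curation_table(v$variant_key, 5L, "none")
  tri <- run_triage(v, tiny_panel(), cur)
  expect_equal(tri$status, "pv")
  expect_equal(tri$acmg_class, 5L)
})

test_that("triage is monotone: enabling filters never enlarges the retained set", {
  set.seed(42)
  panel <- tiny_panel()
  open_cfg <- triage_config(min_depth = 1e-9, min_gq = 1e-9, min_vaf = 1e-9,
                            max_af = 1, max_af_high_freq_genes = 1,
                            excluded_consequences = character(0))
  for (rep in 1:5) {
    n <- 40
    v <- variant_table(
      patient_id = sprintf("P%02d", sample(5, n, TRUE)),
      chrom = "1", pos = sample.int(1e6, n), ref = "A", alt = "C",
      depth = sample(c(3, 8, 40), n, TRUE),
      gq = sample(c(10, 20, 99), n, TRUE),
      vaf = sample(c(0.1, 0.2, 0.5), n, TRUE),
      gene = sample(c("TP53", "RB1", "OFFPANEL"), n, TRUE),
      consequence = sample(c("missense_variant", "intron_variant",
                             "stop_gained"), n, TRUE),
      gnomad_max_af = sample(c(0, 0.005, 0.05), n, TRUE),
      cadd_phred = round(runif(n, 0, 40), 1),
      acmg_class = sample(c(2L, 3L, 4L, 5L), n, TRUE))
    strict <- run_triage(v, panel)
    open <- run_triage(v, panel, config = open_cfg)
    retained <- function(x) x$variant_key[x$status != "excluded"]
    expect_true(all(retained(strict) %in% retained(open)))

    # idempotence: re-triaging the retained set changes nothing
    keep <- strict[strict$status != "excluded",
                   setdiff(names(strict),
                           c("status", "failed_filters", "splice_significant",
                             "onset_override"))]
    again <- run_triage(keep, panel)
    expect_equal(again$status,
                 strict$status[strict$status != "excluded"])

    # oracle: the cascade equals the brute-force conjunction of predicates
    oracle <- passes_call_quality(v) & passes_consequence_filter(v) &
      (!is.na(v$gene) & v$gene %in% panel$symbol) &
      passes_frequency_filter(v, panel)
    expect_equal(strict$status != "excluded", unname(oracle))
  }
})
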