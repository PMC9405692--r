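test_that("allele frequency is alt/depth, missing at zero depth", {
  expect_equal(round_half_up(allele_frequency(144, 149), 2), 0.97)
  expect_equal(allele_frequency(0, 106), 0)
  expect_equal(round_half_up(allele_frequency(454, 1979), 6), 0.229409)
  expect_true(is.na(allele_frequency(0, 0)))
  expect_error(allele_frequency(5, 3))
})

test_that("Fisher exact p matches the enumeration oracle and stats::fisher.test", {
  expect_equal(fisher_exact_2x2(5, 5, 5, 5), 1)
  expect_equal(fisher_exact_2x2(0, 0, 0, 0), 1)

  cases <- rbind(c(8, 2, 0, 10), c(144, 5, 0, 106), c(3, 297, 0, 300),
                 c(20, 0, 50, 50), c(1, 0, 0, 1), c(7, 13, 2, 18))
  for (i in seq_len(nrow(cases))) {
    cs <- cases[i, ]
    got <- fisher_exact_2x2(cs[1], cs[2], cs[3], cs[4])
    expect_equal(got, oracle_fisher_p(cs[1], cs[2], cs[3], cs[4]),
                 tolerance = 1e-12)
    ft <- fisher.test(matrix(cs, 2, byrow = TRUE))$p.value
    expect_equal(got, ft, tolerance = 1e-9)
  }
  expect_lt(fisher_exact_2x2(144, 5, 0, 106), 1e-10)
})

test_that("site classification separates somatic, germline and LOH", {
  cfg <- filter_config()
  # tumor 76/128 vs gDNA 0/324: high-confidence somatic
  call <- classify_site(counts(128, 76), counts(324, 0), cfg)
  expect_equal(call$status, "somatic")
  expect_lt(call$fisher_p, 1e-10)

  # het in both compartments at depth: germline
  expect_equal(classify_site(counts(1000, 500), counts(1000, 500))$status,
               "germline")
  # germline het, tumor swept to near-homozygous: LOH
  expect_equal(classify_site(counts(1000, 950), counts(1000, 500))$status,
               "LOH")
  # zero-depth tumor: unknown, AF missing
  unk <- classify_site(counts(0, 0), counts(100, 50))
  expect_equal(unk$status, "unknown")
  expect_true(is.na(unk$tumor_af))
})

test_that("retention thresholds behave literally at their boundaries", {
  cfg <- filter_config()
  mk <- function(t_depth, t_alt, g_depth, g_alt, status = "somatic")
    data.frame(tumor_depth = t_depth, tumor_alt = t_alt,
               tumor_af = ifelse(t_depth > 0, t_alt / t_depth, NA),
               gdna_depth = g_depth, gdna_alt = g_alt,
               gdna_af = ifelse(g_depth > 0, g_alt / g_depth, NA),
               fisher_p = 1e-12, status = status, stringsAsFactors = FALSE)

  out <- apply_retention_filters(mk(9, 5, 200, 0), cfg)
  expect_false(out$retained)
  expect_match(out$reasons, "min_coverage")
  expect_true(apply_retention_filters(mk(10, 5, 200, 0), cfg)$retained)

  # "at least 3 reads" and "at least 1% AF" are inclusive
  expect_true(apply_retention_filters(mk(300, 3, 300, 0), cfg)$retained)
  expect_match(apply_retention_filters(mk(300, 2, 300, 0), cfg)$reasons,
               "min_alt_tumor")
  # "less than 1% in gDNA" is exclusive: AF exactly 0.01 fails
  expect_match(apply_retention_filters(mk(200, 50, 100, 1), cfg)$reasons,
               "max_gdna_af")
  expect_true(apply_retention_filters(mk(200, 50, 1000, 9), cfg)$retained)
})

test_that("strand-biased calls are discarded via the Fisher strand test", {
  cfg <- filter_config()
  expect_true(strand_bias_test(20, 0, 50, 50, cfg))
  expect_false(strand_bias_test(10, 10, 50, 50, cfg))
  # significant imbalance but below the skew floor is tolerated
  expect_false(strand_bias_test(60, 40, 20, 80, cfg))
  # no strand info, no flag
  expect_false(strand_bias_test(NA, NA, NA, NA, cfg))

  call <- data.frame(tumor_depth = 120, tumor_alt = 20, tumor_af = 20 / 120,
                     gdna_depth = 300, gdna_alt = 0, gdna_af = 0,
                     fisher_p = 1e-12, status = "somatic",
                     alt_fwd = 20, alt_rev = 0, ref_fwd = 50, ref_rev = 50)
  out <- apply_retention_filters(call, cfg)
  expect_false(out$retained)
  expect_match(out$reasons, "strand_bias")
})

test_that("filtering conserves records and lowering min_tumor_af only grows the retained set", {
  spec <- cohort_spec(n_patients = 4, germline_het_sites_per_patient = 10,
                      somatic_sites_per_patient = 5, seed = 21,
                      somatic_af_range = c(0.02, 0.6))
  co <- simulate_cohort(spec)
  trios <- do.call(rbind, lapply(co$trios, function(tr) tr$records))
  calls <- classify_site(counts(trios$tumor_depth, trios$tumor_alt),
                         counts(trios$gdna_depth, trios$gdna_alt))
  strict <- apply_retention_filters(calls, filter_config(min_tumor_af = 0.05))
  loose <- apply_retention_filters(calls, filter_config(min_tumor_af = 0.01))
  expect_equal(sum(strict$retained) + sum(!strict$retained), nrow(calls))
  expect_true(all(nzchar(strict$reasons[!strict$retained])))
  expect_true(all(which(strict$retained) %in% which(loose$retained)))
})

test_that("population catalog and SIFT effect filters drop the right calls", {
  cfg <- filter_config()
  calls <- data.frame(key = c("rs12573787", "rs_rare", "not_in_catalog",
                              "rs_tolerated", "rs_damaging"),
                      retained = TRUE, reasons = "",
                      stringsAsFactors = FALSE)
  catalog <- data.frame(
    key = c("rs12573787", "rs_rare", "rs_tolerated", "rs_damaging"),
    maf = c(0.16, NA, NA, NA),
    af_1000g = c(NA, 0.0002, NA, NA),
    af_gnomad = c(NA, 2e-05, NA, NA),
    sift = c(NA, NA, 0.5, 0.01),
    stringsAsFactors = FALSE)
  out <- filter_population_and_effect(calls, catalog, cfg)
  expect_false(out$retained[out$key == "rs12573787"])   # 1000G AF 0.16: common
  expect_true(out$retained[out$key == "rs_rare"])       # rare catalogued variant kept
  expect_true(out$retained[out$key == "not_in_catalog"])
  expect_false(out$retained[out$key == "rs_tolerated"]) # SIFT 0.5 tolerated
  expect_true(out$retained[out$key == "rs_damaging"])   # SIFT 0.01 damaging

  inv <- filter_population_and_effect(calls, catalog,
                                      filter_config(sift_damaging_is_high = TRUE))
  expect_true(inv$retained[inv$key == "rs_tolerated"])
  expect_false(inv$retained[inv$key == "rs_damaging"])
})

test_that("gene frequency and VAF summaries follow the calls", {
  empty <- summarize_gene_frequencies(
    data.frame(gene = character(), patient = character()))
  expect_equal(nrow(empty), 0)

  calls <- data.frame(
    gene = c("TP53", "TP53", "TP53", "PTEN", "PTEN", "EGFR", "TP53"),
    patient = c("1", "2", "3", "1", "2", "1", "1"),
    tumor_af = c(0.42, 0.3, 0.9, 0.5, 0.85, 0.2, 0.6),
    retained = c(rep(TRUE, 6), FALSE), stringsAsFactors = FALSE)
  tab <- summarize_gene_frequencies(calls)
  expect_equal(tab$gene[1], "TP53")
  expect_equal(tab$n_patients, c(3, 2, 1))
  expect_equal(tab$rank, c(1, 2, 3))

  v <- vaf_by_gene(calls)
  expect_equal(v$TP53, c(0.3, 0.42, 0.9))
  expect_false("ATRX" %in% names(v))
  expect_equal(vaf_by_gene(calls[calls$gene == "EGFR", ])$EGFR, 0.2)
})

test_that("somatic recovery on generator truth: high-AF injections read back", {
  spec <- cohort_spec(n_patients = 6, germline_het_sites_per_patient = 8,
                      somatic_sites_per_patient = 4, seed = 77,
                      somatic_af_range = c(0.85, 0.95),
                      depth_model = c(gdna = 1000, tdna = 200, ccfdna = 2000))
  co <- simulate_cohort(spec)
  trios <- do.call(rbind, lapply(co$trios, function(tr) tr$records))
  calls <- cbind(trios[c("gene", "patient", "label")],
                 classify_site(counts(trios$tumor_depth, trios$tumor_alt),
                               counts(trios$gdna_depth, trios$gdna_alt)))
  calls <- apply_retention_filters(calls)
  # homozygous-like injections: per-gene medians sit high
  v <- vaf_by_gene(calls)
  expect_true(all(vapply(v, median, 0) > 0.75))
  # recovered per-gene patient counts equal the generator truth
  truth_tab <- summarize_gene_frequencies(
    cbind(trios[trios$label == "somatic", c("gene", "patient")],
          retained = TRUE))
  got_tab <- summarize_gene_frequencies(calls)
  expect_equal(got_tab[c("gene", "n_patients")],
               truth_tab[c("gene", "n_patients")])
})
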