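small_spec <- function(...) {
  cohort_spec(n_patients = 3, germline_het_sites_per_patient = 4,
              somatic_sites_per_patient = 2, ...)
}

test_that("a somatic site with no ctDNA and no error yields zero plasma alt reads", {
  spec <- small_spec(ctdna_fraction_range = c(0, 0), error_rate = 0,
                     seed = 11)
  for (i in 1:3) {
    tr <- simulate_trio(spec, i)
    som <- tr$records[tr$records$label == "somatic", ]
    expect_equal(som$ccf_alt, rep(0, nrow(som)))
    expect_equal(som$gdna_alt, rep(0, nrow(som)))
  }
})

test_that("germline het sites sit near AF 0.5 in all three compartments", {
  spec <- cohort_spec(n_patients = 1, germline_het_sites_per_patient = 30,
                      somatic_sites_per_patient = 0, error_rate = 0,
                      depth_model = c(gdna = 1000, tdna = 1000, ccfdna = 1000),
                      seed = 5)
  tr <- simulate_trio(spec, 1)
  # central 99% binomial band at n = 1000, p = 0.5
  lo <- qbinom(0.005, 1000, 0.5); hi <- qbinom(0.995, 1000, 0.5)
  for (col in c("gdna_alt", "tumor_alt", "ccf_alt")) {
    x <- tr$records[[col]]
    expect_gt(mean(x >= lo & x <= hi), 0.9)
    expect_lt(abs(mean(x / 1000) - 0.5), 0.02)
  }
})

test_that("plasma counts follow the ctDNA mixture law f*a + (1-f)*e", {
  # Monte-Carlo oracle: 0.1 * 0.5 + 0.9 * 0.001 = 0.0509
  spec <- cohort_spec(n_patients = 1, germline_het_sites_per_patient = 0,
                      somatic_sites_per_patient = 1,
                      somatic_af_range = c(0.5, 0.5),
                      ctdna_fraction_range = c(0.1, 0.1), error_rate = 0.001,
                      depth_model = c(gdna = 200, tdna = 200, ccfdna = 2000))
  afs <- vapply(1:600, function(s) {
    spec$seed <- s
    tr <- simulate_trio(spec, 1)
    tr$records$ccf_alt / tr$records$ccf_depth
  }, 0)
  expect_lt(abs(mean(afs) - 0.0509), 0.005)
  # and within 3 standard errors of the mixture rate
  expect_lt(abs(mean(afs) - 0.0509), 3 * sd(afs) / sqrt(length(afs)))
})

test_that("identical spec and seed reproduce the cohort exactly", {
  a <- simulate_cohort(small_spec(seed = 42))
  b <- simulate_cohort(small_spec(seed = 42))
  expect_identical(a$truth, b$truth)
  expect_identical(a$trios[[2]]$records, b$trios[[2]]$records)
})

test_that("truth labels are conserved at the requested per-patient counts", {
  spec <- small_spec(seed = 3)
  co <- simulate_cohort(spec)
  tab <- table(co$truth$patient, co$truth$label)
  expect_true(all(tab[, "germline"] == spec$germline_het_sites_per_patient))
  expect_true(all(tab[, "somatic"] == spec$somatic_sites_per_patient))
})

test_that("zero depth is rejected at spec construction", {
  expect_error(cohort_spec(depth_model = c(gdna = 0, tdna = 100, ccfdna = 100)),
               "depth_model")
})

test_that("cohort round-trips through VCF byte-identically and count-exactly", {
  spec <- small_spec(seed = 9)
  co <- simulate_cohort(spec)
  d1 <- file.path(tempdir(), "cohort_a"); d2 <- file.path(tempdir(), "cohort_b")
  write_cohort(co, d1)
  write_cohort(simulate_cohort(spec), d2)
  f1 <- list.files(d1, full.names = TRUE); f2 <- list.files(d2, full.names = TRUE)
  expect_identical(basename(f1), basename(f2))
  for (i in seq_along(f1))
    expect_identical(readBin(f1[i], "raw", 1e6), readBin(f2[i], "raw", 1e6))
  back <- read_cohort(d1)
  orig <- do.call(rbind, lapply(co$trios, function(tr) tr$records))
  orig <- orig[order(orig$patient, orig$chrom, orig$pos), ]
  back <- back[order(back$patient, back$chrom, back$pos), ]
  for (col in c("chrom", "pos", "ref", "alt", "gdna_depth", "gdna_alt",
                "tumor_depth", "tumor_alt", "ccf_depth", "ccf_alt"))
    expect_equal(unname(back[[col]]), unname(orig[[col]]))
})

test_that("UMI family expansion keeps the read/family accounting", {
  r <- simulate_umi_reads(1, alt_molecules = 1, duplicates = 5,
                          duplicate_error = 0, seed = 1)
  expect_equal(nrow(r), 5)
  expect_equal(length(unique(r$umi)), 1)
  expect_true(all(r$allele == "alt"))

  r <- simulate_umi_reads(1000, alt_molecules = 100, duplicates = 3,
                          duplicate_error = 0, seed = 2)
  expect_equal(length(unique(r$umi)), 1000)
  cc <- collapse_umi(r)
  expect_equal(cc$depth, 1000)
  expect_equal(cc$alt, 100)
  # sum of family sizes equals total duplicate reads
  expect_equal(sum(table(r$umi)), nrow(r))
})

test_that("majority-vote recovery under duplicate errors matches exact enumeration", {
  e <- 0.4; d <- 3; n_fam <- 4000
  p_recover <- oracle_majority_recovery(d, e)  # 0.648 for (3, 0.4)
  expect_equal(p_recover, 0.648)
  r <- simulate_umi_reads(n_fam, alt_molecules = n_fam, duplicates = d,
                          duplicate_error = e, seed = 31)
  cc <- collapse_umi(r)
  # observed recovery within a 99.9% binomial band of the enumerated rate
  band <- qbinom(c(5e-4, 1 - 5e-4), n_fam, p_recover)
  expect_gte(cc$alt, band[1])
  expect_lte(cc$alt, band[2])
})

test_that("fragment profiles peak at the mononucleosome mode", {
  prof <- simulate_fragment_profile(fragment_length_model(), 1e5, seed = 8)
  mode_bp <- prof$length_bp[which.max(prof$abundance)]
  expect_lt(abs(mode_bp - 167), 10)
  expect_gte(min(prof$length_bp), 1)

  contaminated <- simulate_fragment_profile(
    fragment_length_model(dimer_weight = 0, trimer_weight = 0,
                          contaminant_weight = 1), 1e4, seed = 8)
  expect_true(all(contaminated$length_bp > 2000))
  expect_equal(classify_qc(contaminated)$status, "fail")

  half <- simulate_fragment_profile(
    fragment_length_model(dimer_weight = 0, trimer_weight = 0,
                          contaminant_weight = 0.5), 1e5, seed = 13)
  frac <- quantify_window(half, 100, 500) / sum(half$abundance)
  expect_lt(abs(frac - 0.5), 0.01)
})
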