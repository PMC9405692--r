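test_that("plasma-only selection enforces germline absence and plasma support", {
  trios <- data.frame(
    patient = c("6", "g", "32"),
    gdna_depth = c(225, 100, 79), gdna_alt = c(0, 50, 1),
    ccf_depth = c(201, 200, 150), ccf_alt = c(5, 50, 62))
  strict <- select_ccfdna_only(trios)
  expect_equal(strict$patient, "6")        # gDNA 0/225, ccfDNA 5/201
  relaxed <- select_ccfdna_only(trios, relaxed = TRUE)
  expect_setequal(relaxed$patient, c("6", "32"))  # 1/79 tolerated when relaxed
  # a truly germline site never passes either rule
  expect_false("g" %in% relaxed$patient)
})

test_that("tier assignment follows the fixed rule order", {
  cfg <- triage_config()
  rec <- function(key, patient = "p1")
    data.frame(patient = patient, key = key, ccf_depth = 200, ccf_alt = 5,
               gdna_depth = 200, gdna_alt = 0,
               gdna_af_value = 0, ccf_af_value = 0.025,
               stringsAsFactors = FALSE)
  ann <- data.frame(
    key = c("rs121913279", "rs12573787", "rs_cosmic_rare", "rs_cosmic_common"),
    clinsig = c("pathogenic FDA recognized", "benign", "uncertain significance",
                "uncertain significance"),
    cosmic_registered = c(FALSE, FALSE, TRUE, TRUE),
    maf = c(NA, 0.16, 2e-04, 0.05), af_1000g = NA, af_gnomad = NA,
    stringsAsFactors = FALSE)

  # pathogenic clinsig, no catalogs
  t1 <- classify_tier(rec("rs121913279"), ann, config = cfg)
  expect_equal(as.character(t1$tier), "PATHOGENIC_CCFDNA_ONLY")
  # benign carrier, no catalogs
  t2 <- classify_tier(rec("rs12573787"), ann, config = cfg)
  expect_equal(as.character(t2$tier), "CARRIER_BENIGN")
  # COSMIC + rare qualifies; COSMIC + common does not
  expect_equal(as.character(classify_tier(rec("rs_cosmic_rare"), ann,
                                          config = cfg)$tier),
               "PATHOGENIC_CCFDNA_ONLY")
  expect_equal(as.character(classify_tier(rec("rs_cosmic_common"), ann,
                                          config = cfg)$tier),
               "DISCARDED")
  # unannotated, no catalog: discarded
  expect_equal(as.character(classify_tier(rec("chrZ:1:A:T"), ann,
                                          config = cfg)$tier),
               "DISCARDED")

  # cohort confirmation outranks annotation; same-patient tumor match
  # outranks everything
  catalog <- data.frame(key = "rs121913279", source = c("prior", "current"))
  t3 <- classify_tier(rec("rs121913279"), ann, catalog, config = cfg)
  expect_equal(as.character(t3$tier), "COHORT_CURRENT_CONFIRMED")
  t4 <- classify_tier(rec("rs121913279"), ann,
                      data.frame(key = "rs121913279", source = "prior"),
                      config = cfg)
  expect_equal(as.character(t4$tier), "COHORT_PRIOR_CONFIRMED")
  own <- data.frame(key = "rs121913279", patient = "p1")
  t5 <- classify_tier(rec("rs121913279"), ann, catalog, own, cfg)
  expect_equal(as.character(t5$tier), "CTDNA_CONFIRMED")
})

test_that("tier assignment is total and partitions the selected records", {
  spec <- cohort_spec(n_patients = 5, seed = 33)
  co <- simulate_cohort(spec)
  trios <- do.call(rbind, lapply(co$trios, function(tr) tr$records))
  trios$key <- variant_key(trios$chrom, trios$pos, trios$ref, trios$alt)
  sel <- select_ccfdna_only(trios)
  tiered <- classify_tier(sel)
  expect_equal(sum(table(tiered$tier)), nrow(sel))
  expect_false(any(is.na(tiered$tier)))
  # the trail reconstructs the tier
  expect_true(all((tiered$tier == "DISCARDED") ==
                    (tiered$tier_rule == "no_rule_matched")))
  # subadditivity of patient counts over tier unions
  a <- count_patients_tiered(tiered, "PATHOGENIC_CCFDNA_ONLY")
  b <- count_patients_tiered(tiered, "DISCARDED")
  ab <- count_patients_tiered(tiered, c("PATHOGENIC_CCFDNA_ONLY", "DISCARDED"))
  expect_lte(ab, a + b)
})

test_that("fixture triage reproduces the study's patient counts", {
  rep <- run_fixture_report()
  expect_equal(rep$pathogenic_ccfdna_patients, 25)
  expect_equal(rep$cohort_confirmed_patients, 16)
  # all 36 plasma-only rows survive selection and tier as pathogenic
  expect_equal(nrow(rep$outputs$pathogenic), 36)
  expect_true(all(rep$outputs$pathogenic$tier == "PATHOGENIC_CCFDNA_ONLY"))
  # prior rows land in the prior tier, current rows in the current tier
  t34 <- rep$outputs$cohort_confirmed
  expect_equal(sum(t34$tier == "COHORT_PRIOR_CONFIRMED"), 12)
  expect_equal(sum(t34$tier == "COHORT_CURRENT_CONFIRMED"), 9)
})

test_that("triage tables mirror tier membership, empty tiers stay header-only", {
  fix <- load_fixture_tables()
  t2 <- fix$ccfdna_only
  t2$key <- variant_key(t2$chrom, t2$pos, rsid = t2$rsid)
  cats <- fixture_catalogs(fix)
  tiered <- classify_tier(select_ccfdna_only(t2), cats$annotation)
  out <- emit_triage_tables(tiered)
  expect_equal(nrow(out$tables$PATHOGENIC_CCFDNA_ONLY), 36)
  expect_equal(nrow(out$tables$CARRIER_BENIGN), 0)
  expect_named(out$tables, TRIAGE_TIERS)
  expect_equal(sort(unique(out$patient_summary$patient)),
               sort(unique(t2$patient)))
  expect_true(all(out$patient_summary$alteration == "SNV"))
})
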