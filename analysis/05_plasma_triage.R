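#!/usr/bin/env Rscript
# Stage 5: triage of plasma variants absent from germline DNA, against the
# packaged annotation and cohort catalogs - reproducing the study's
# pathogenic plasma-only and cohort-confirmed patient counts.

library(plasmatriage)

fix <- load_fixture_tables()
cats <- fixture_catalogs(fix)

# pathogenic plasma-only tier (COSMIC-registered table)
t2 <- fix$ccfdna_only
t2$key <- variant_key(t2$chrom, t2$pos, rsid = t2$rsid)
tier2 <- classify_tier(select_ccfdna_only(t2), cats$annotation)
cat("Plasma-only pathogenic tier:",
    count_patients_tiered(tier2, "PATHOGENIC_CCFDNA_ONLY"),
    "patients across", nrow(tier2), "variants\n")

# cohort-confirmed tiers (prior + current confirmation tables)
t3 <- fix$prior_cohort; t3$key <- variant_key(NA, NA, rsid = t3$rsid)
t4 <- fix$current_cohort
t4$key <- variant_key(t4$chrom, t4$pos, t4$ref, t4$alt, t4$rsid)
cols <- c("gene", "patient", "key", "diagnosis", "gdna_depth", "gdna_alt",
          "ccf_depth", "ccf_alt")
confirm <- rbind(t3[cols], t4[cols])
tier34 <- classify_tier(select_ccfdna_only(confirm, relaxed = TRUE),
                        cats$annotation, cats$cohort)
cat("Cohort-confirmed tiers:",
    count_patients_tiered(tier34, c("COHORT_PRIOR_CONFIRMED",
                                    "COHORT_CURRENT_CONFIRMED",
                                    "CARRIER_BENIGN")),
    "patients (prior:", sum(tier34$tier == "COHORT_PRIOR_CONFIRMED"),
    "rows, current:", sum(tier34$tier == "COHORT_CURRENT_CONFIRMED"),
    "rows)\n")

out <- emit_triage_tables(rbind(
  tier2[intersect(names(tier2), names(tier34))],
  tier34[intersect(names(tier2), names(tier34))]))
dir.create("results", showWarnings = FALSE)
for (tier in names(out$tables)) {
  tab <- out$tables[[tier]]
  if (nrow(tab) > 0)
    write.table(tab, file.path("results",
                               paste0("triage_", tolower(tier), ".tsv")),
                sep = "\t", quote = FALSE, row.names = FALSE)
}
write.table(out$patient_summary, "results/triage_patient_summary.tsv",
            sep = "\t", quote = FALSE, row.names = FALSE)
cat("Wrote per-tier tables and the patient-level summary under results/\n")
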