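#!/usr/bin/env Rscript
# Stage 1: generate the synthetic matched-trio cohort used by the
# downstream analyses: 84 patients (mostly grade-4 glioma, a few grade-3,
# PCNSL and metastatic patients), each with germline heterozygous sites,
# clonal tumor somatic sites, and plasma counts mixing ctDNA signal at the
# patient's ctDNA fraction with sequencing error.

library(plasmatriage)

spec <- cohort_spec(seed = 1L)
cohort <- simulate_cohort(spec)

out_dir <- "results/cohort"
write_cohort(cohort, out_dir)

truth <- cohort$truth
cat("Simulated", spec$n_patients, "patients,",
    nrow(truth), "variant sites:\n")
print(table(truth$label))
cat("\nDiagnosis classes:\n")
print(table(classify_diagnosis(
  vapply(cohort$trios, `[[`, "", "diagnosis"))))
cat("\nctDNA fraction range realized: ",
    sprintf("%.3f-%.3f", min(truth$true_ctdna_fraction),
            max(truth$true_ctdna_fraction)), "\n", sep = "")
cat("Wrote per-patient trio VCFs and truth table under ", out_dir, "\n",
    sep = "")
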