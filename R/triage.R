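#' Plasma-only triage configuration
#'
#' @param min_plasma_alt minimum plasma alt reads for a record to enter
#'   triage. Default 2: the plasma-only report tables retain variants with
#'   as few as 2 supporting consensus reads, below the concordance stage's
#'   threshold of 3.
#' @param strict_gdna_alt_max maximum germline alt reads under the strict
#'   germline-absence rule used for the pathogenic plasma-only tier
#'   (default 0: absent means absent).
#' @param relaxed_gdna_af_max,relaxed_gdna_alt_max the relaxed
#'   germline-absence rule used for cohort-confirmed tiers: germline AF
#'   strictly below `relaxed_gdna_af_max` and at most
#'   `relaxed_gdna_alt_max` alt reads. Defaults 0.1 and 3: the rule is
#'   driven by the absolute alt-read ceiling (a stray read or three), and
#'   the AF guard only excludes genuinely germline-looking sites - the
#'   printed cohort-confirmation rows run up to 2 alt reads of 39
#'   (AF 0.051).
#' @param rare_af_max population-AF ceiling for the COSMIC+rarity arm of
#'   the pathogenic tier. Default 0.001: uncertain-significance variants at
#'   population AF around 1e-4 qualify, common polymorphisms do not.
#' @return named list.
#' @export
triage_config <- function(min_plasma_alt = 2, strict_gdna_alt_max = 0,
                          relaxed_gdna_af_max = 0.1,
                          relaxed_gdna_alt_max = 3,
                          rare_af_max = 0.001) {
  stopifnot(min_plasma_alt >= 0, strict_gdna_alt_max >= 0,
            relaxed_gdna_af_max >= 0, relaxed_gdna_af_max <= 1,
            rare_af_max >= 0, rare_af_max <= 1)
  as.list(environment())
}

#' Select plasma variants absent from germline DNA
#'
#' Retains records supported by at least `min_plasma_alt` plasma reads
#' whose germline compartment is compatible with absence: either strictly
#' (at most `strict_gdna_alt_max` alt reads) or, when `relaxed = TRUE`,
#' under the relaxed rule (AF below `relaxed_gdna_af_max` with at most
#' `relaxed_gdna_alt_max` alt reads) that admits the stray germline read
#' or two seen in cohort-confirmed variants.
#'
#' @param trios data frame with `gdna_depth`, `gdna_alt`, `ccf_depth`,
#'   `ccf_alt`.
#' @param config a [triage_config()].
#' @param relaxed use the relaxed germline-absence rule.
#' @return the retained rows, with `gdna_af`/`ccf_af` value columns added.
#' @export
select_ccfdna_only <- function(trios, config = triage_config(),
                               relaxed = FALSE) {
  af_g <- allele_frequency(trios$gdna_alt, trios$gdna_depth)
  gdna_absent <- if (relaxed) {
    (is.na(af_g) | af_g < config$relaxed_gdna_af_max) &
      trios$gdna_alt <= config$relaxed_gdna_alt_max
  } else {
    trios$gdna_alt <= config$strict_gdna_alt_max
  }
  keep <- gdna_absent & trios$ccf_alt >= config$min_plasma_alt
  out <- trios[keep, , drop = FALSE]
  out$gdna_af_value <- af_g[keep]
  out$ccf_af_value <- allele_frequency(out$ccf_alt, out$ccf_depth)
  rownames(out) <- NULL
  out
}

#' Assign triage tiers to plasma-only variants
#'
#' Each record receives exactly one tier by the first matching rule, in
#' fixed order:
#' \enumerate{
#'   \item `CTDNA_CONFIRMED` - the identity is among the same patient's
#'     tumor somatic calls;
#'   \item `COHORT_CURRENT_CONFIRMED` - identity confirmed somatic in the
#'     current cohort's tumors;
#'   \item `COHORT_PRIOR_CONFIRMED` - identity in the prior-cohort somatic
#'     catalog;
#'   \item `PATHOGENIC_CCFDNA_ONLY` - pathogenic-like clinical
#'     significance, or COSMIC-registered and rare in the population
#'     (AF at most `rare_af_max`; absence from population databases counts
#'     as rare);
#'   \item `CARRIER_BENIGN` - benign clinical significance;
#'   \item `DISCARDED` - everything else.
#' }
#' Missing annotation is treated as unannotated (no COSMIC registration,
#' clinsig `none`).
#'
#' @param records data frame from [select_ccfdna_only()] with a `key`
#'   column ([variant_key()]) and `patient`.
#' @param annotation catalog with `key`, `clinsig`, `cosmic_registered` and
#'   population AF columns (`maf`, `af_1000g`, `af_gnomad`).
#' @param cohort_catalog data frame with `key` and `source`
#'   (`"prior"`/`"current"`); may be empty or `NULL`.
#' @param current_somatic optional data frame of the current run's tumor
#'   somatic calls (`key`, `patient`) used for the same-patient
#'   confirmation rule.
#' @param config a [triage_config()].
#' @return `records` with `tier` and `tier_rule` (the rule that fired)
#'   columns.
#' @export
classify_tier <- function(records, annotation = NULL, cohort_catalog = NULL,
                          current_somatic = NULL,
                          config = triage_config()) {
  n <- nrow(records)
  idx <- if (!is.null(annotation)) match(records$key, annotation$key)
         else rep(NA_integer_, n)
  pick <- function(col, default) {
    v <- if (!is.null(annotation)) annotation[[col]] else NULL
    out <- if (is.null(v)) rep(NA, n) else v[idx]
    out[is.na(idx)] <- NA
    out
  }
  clinsig <- normalize_clinsig(pick("clinsig"))
  cosmic <- pick("cosmic_registered")
  cosmic[is.na(cosmic)] <- FALSE
  pop_af <- pmax(as.numeric(pick("maf")), as.numeric(pick("af_1000g")),
                 as.numeric(pick("af_gnomad")), 0, na.rm = TRUE)

  in_src <- function(src) {
    if (is.null(cohort_catalog) || nrow(cohort_catalog) == 0) return(rep(FALSE, n))
    records$key %in% cohort_catalog$key[cohort_catalog$source == src]
  }
  same_patient <- if (is.null(current_somatic) || nrow(current_somatic) == 0) {
    rep(FALSE, n)
  } else {
    paste(records$key, records$patient) %in%
      paste(current_somatic$key, current_somatic$patient)
  }

  pathogenic_like <- clinsig %in% PATHOGENIC_CLINSIG |
    (as.logical(cosmic) & pop_af <= config$rare_af_max)

  tier <- rep("DISCARDED", n)
  rule <- rep("no_rule_matched", n)
  assign_tier <- function(cond, t, r) {
    hit <- cond & tier == "DISCARDED" & rule == "no_rule_matched"
    tier[hit] <<- t; rule[hit] <<- r
  }
  assign_tier(same_patient, "CTDNA_CONFIRMED", "matched_own_tumor_somatic")
  assign_tier(in_src("current"), "COHORT_CURRENT_CONFIRMED",
              "identity_in_current_cohort")
  assign_tier(in_src("prior"), "COHORT_PRIOR_CONFIRMED",
              "identity_in_prior_cohort")
  assign_tier(pathogenic_like, "PATHOGENIC_CCFDNA_ONLY",
              "clinsig_pathogenic_or_cosmic_rare")
  assign_tier(clinsig == "benign", "CARRIER_BENIGN", "clinsig_benign")
  records$tier <- factor(tier, levels = TRIAGE_TIERS)
  records$tier_rule <- rule
  records
}

#' Count distinct patients in a tier set
#'
#' @param calls output of [classify_tier()].
#' @param tiers character vector of tier names to count over.
#' @return integer count of distinct patients with at least one call in
#'   the requested tiers.
#' @export
count_patients_tiered <- function(calls, tiers) {
  stopifnot(all(tiers %in% TRIAGE_TIERS))
  length(unique(calls$patient[calls$tier %in% tiers]))
}

#' Per-tier triage tables
#'
#' Splits tiered calls into one report table per tier (header-only data
#' frames for empty tiers), AFs formatted at report precision, plus a
#' patient-by-gene presence summary with the alteration class
#' (SNV/insertion/deletion when `ref`/`alt` are available).
#'
#' @param calls output of [classify_tier()].
#' @return list with `tables` (named by tier) and `patient_summary`.
#' @export
emit_triage_tables <- function(calls) {
  calls$ccf_af <- format_af(calls$ccf_af_value, 3)
  if (!is.null(calls$gdna_af_value))
    calls$gdna_af <- format_af(calls$gdna_af_value, 2)
  drop <- c("gdna_af_value", "ccf_af_value")
  tables <- lapply(TRIAGE_TIERS, function(t)
    calls[calls$tier == t, setdiff(names(calls), drop), drop = FALSE])
  names(tables) <- TRIAGE_TIERS
  kept <- calls[calls$tier != "DISCARDED", , drop = FALSE]
  alteration <- if (!is.null(kept$ref) && !is.null(kept$alt)) {
    ifelse(nchar(kept$ref) < nchar(kept$alt), "ins",
           ifelse(nchar(kept$ref) > nchar(kept$alt), "del", "SNV"))
  } else rep("SNV", nrow(kept))
  patient_summary <- if (nrow(kept) > 0) {
    ps <- data.frame(patient = kept$patient, gene = kept$gene,
                     alteration = alteration, tier = as.character(kept$tier),
                     stringsAsFactors = FALSE)
    ps[order(ps$patient, ps$gene), , drop = FALSE]
  } else {
    data.frame(patient = character(), gene = character(),
               alteration = character(), tier = character(),
               stringsAsFactors = FALSE)
  }
  rownames(patient_summary) <- NULL
  list(tables = tables, patient_summary = patient_summary)
}
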