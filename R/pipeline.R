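#' Pipeline run configuration
#'
#' One validated object holding every stage's thresholds plus the input
#' choice (a synthetic cohort spec, or the packaged fixture tables).
#' Unknown keys are rejected so configuration typos fail loudly.
#'
#' @param input `"simulate"` or `"fixtures"`.
#' @param seed integer seed threaded to every stochastic stage.
#' @param cohort a [cohort_spec()] (used when `input = "simulate"`; its
#'   own seed is overridden by `seed`).
#' @param filters a [filter_config()].
#' @param detection a [detection_config()].
#' @param triage a [triage_config()].
#' @param cna a [cna_config()].
#' @param stages character vector of stages to run, in order, among
#'   `"qc"`, `"somatic"`, `"ctdna"`, `"triage"`.
#' @param ... rejected; catches misspelled arguments.
#' @return named list of class `run_config`.
#' @export
run_config <- function(input = c("simulate", "fixtures"), seed = 1L,
                       cohort = cohort_spec(),
                       filters = filter_config(),
                       detection = detection_config(),
                       triage = triage_config(),
                       cna = cna_config(),
                       stages = c("qc", "somatic", "ctdna", "triage"),
                       ...) {
  extra <- list(...)
  if (length(extra) > 0)
    stop("unknown configuration keys: ", paste(names(extra), collapse = ", "))
  input <- match.arg(input)
  stopifnot(all(stages %in% c("qc", "somatic", "ctdna", "triage")))
  cohort$seed <- as.integer(seed)
  structure(list(input = input, seed = as.integer(seed), cohort = cohort,
                 filters = filters, detection = detection, triage = triage,
                 cna = cna, stages = stages), class = "run_config")
}

#' Run the full triage pipeline
#'
#' Wires the stages in order: cohort input (simulation or the packaged
#' fixture tables), fragment QC, somatic calling with retention filters,
#' plasma concordance detection, and plasma-only triage. Rerunning with
#' the same configuration reproduces identical outputs. On synthetic
#' input, detection consumes the simulated plasma counts directly (the
#' UMI-consensus route has its own operations and is exercised by the
#' detection properties).
#'
#' @param config a [run_config()].
#' @return list of class `run_report`: per-stage record counts with
#'   conservation (`input = retained + discarded`), detection counts by
#'   diagnosis class, per-tier patient counts, the stage outputs, and the
#'   configuration hash.
#' @export
run_pipeline <- function(config = run_config()) {
  if (config$input == "fixtures") return(run_fixture_report(config))
  cohort <- simulate_cohort(config$cohort)
  report <- list(config_hash = config_hash(config), stages = list())
  outputs <- list()

  if ("qc" %in% config$stages) {
    verdicts <- lapply(cohort$trios, function(tr)
      classify_qc(tr$fragment_profile))
    qc_pass <- vapply(verdicts, function(v) v$status == "pass", TRUE)
    report$stages$qc <- list(input = length(verdicts),
                             retained = sum(qc_pass),
                             discarded = sum(!qc_pass))
    outputs$qc <- data.frame(
      patient = vapply(cohort$trios, `[[`, "", "patient_id"),
      status = vapply(verdicts, `[[`, "", "status"),
      reason = vapply(verdicts, `[[`, "", "reason"))
  }

  trios <- do.call(rbind, lapply(cohort$trios, function(tr)
    cbind(tr$records, diagnosis = tr$diagnosis)))
  rownames(trios) <- NULL

  if ("somatic" %in% config$stages) {
    calls <- classify_site(
      data.frame(depth = trios$tumor_depth, alt = trios$tumor_alt),
      data.frame(depth = trios$gdna_depth, alt = trios$gdna_alt),
      config$filters)
    calls <- cbind(trios[c("patient", "chrom", "pos", "gene", "ref", "alt",
                           "label", "diagnosis", "ccf_depth", "ccf_alt")],
                   calls[c("tumor_af", "gdna_af", "fisher_p", "status")],
                   tumor_depth = trios$tumor_depth,
                   tumor_alt = trios$tumor_alt,
                   gdna_depth = trios$gdna_depth, gdna_alt = trios$gdna_alt)
    calls <- apply_retention_filters(calls, config$filters)
    calls$key <- variant_key(calls$chrom, calls$pos, calls$ref, calls$alt)
    report$stages$somatic <- list(input = nrow(calls),
                                  retained = sum(calls$retained),
                                  discarded = sum(!calls$retained))
    outputs$somatic <- calls
  }

  if ("ctdna" %in% config$stages && !is.null(outputs$somatic)) {
    som <- outputs$somatic[outputs$somatic$retained, , drop = FALSE]
    det <- detect_ctdna(som, config$detection)
    report$stages$ctdna <- list(input = nrow(det),
                                retained = sum(det$detected),
                                discarded = sum(!det$detected))
    report$detected_patients <- list(
      total = count_detected_patients(det),
      glioma = count_detected_patients(det, "glioma"))
    outputs$ctdna <- det
  }

  if ("triage" %in% config$stages && !is.null(outputs$somatic)) {
    som_set <- outputs$somatic[outputs$somatic$retained,
                               c("key", "patient"), drop = FALSE]
    sel <- select_ccfdna_only(trios_with_key(trios), config$triage)
    tiered <- classify_tier(sel, annotation = NULL, cohort_catalog = NULL,
                            current_somatic = som_set,
                            config = config$triage)
    report$stages$triage <- list(input = nrow(sel), retained = nrow(sel),
                                 discarded = 0L)
    report$tier_patients <- vapply(
      TRIAGE_TIERS, function(t) count_patients_tiered(tiered, t), 0L)
    outputs$triage <- tiered
  }

  report$outputs <- outputs
  report$n_patients <- config$cohort$n_patients
  class(report) <- "run_report"
  report
}

trios_with_key <- function(trios) {
  trios$key <- variant_key(trios$chrom, trios$pos, trios$ref, trios$alt)
  trios
}

# short deterministic hash of the configuration (recorded in the report so
# identical-config runs are recognizably identical)
config_hash <- function(config) {
  s <- paste(deparse(config, control = "all"), collapse = "")
  # polynomial rolling hash over the deparsed text; no digest dependency
  h <- 0
  for (b in utf8ToInt(s)) h <- (h * 31 + b) %% 2147483647
  sprintf("%08x", as.integer(h))
}

#' Reproduce the study's headline counts from the packaged tables
#'
#' Runs the detection and triage stages over the fixture transcriptions of
#' the printed report tables: plasma concordance on the 17-variant table
#' (patients with ctDNA detected overall and among gliomas), pathogenic
#' plasma-only triage on the 36-variant table, and cohort-confirmed triage
#' on the two confirmation tables.
#'
#' @param config a [run_config()] (detection and triage thresholds are
#'   honored).
#' @return list of class `run_report` with `detected_patients`
#'   (`total`, `glioma`), `pathogenic_ccfdna_patients`,
#'   `cohort_confirmed_patients`, and the stage outputs.
#' @export
run_fixture_report <- function(config = run_config(input = "fixtures")) {
  fix <- load_fixture_tables()
  cats <- fixture_catalogs(fix)

  det <- detect_ctdna(fix$concordance, config$detection)
  t2 <- fix$ccfdna_only
  t2$key <- variant_key(t2$chrom, t2$pos, rsid = t2$rsid)
  sel2 <- select_ccfdna_only(t2, config$triage)
  tier2 <- classify_tier(sel2, annotation = cats$annotation,
                         config = config$triage)

  t3 <- fix$prior_cohort
  t3$key <- variant_key(NA, NA, rsid = t3$rsid)
  t4 <- fix$current_cohort
  t4$key <- variant_key(t4$chrom, t4$pos, t4$ref, t4$alt, t4$rsid)
  conf_cols <- c("gene", "patient", "key", "diagnosis", "gdna_depth",
                 "gdna_alt", "ccf_depth", "ccf_alt")
  confirm <- rbind(t3[conf_cols], t4[conf_cols])
  sel34 <- select_ccfdna_only(confirm, config$triage, relaxed = TRUE)
  tier34 <- classify_tier(sel34, annotation = cats$annotation,
                          cohort_catalog = cats$cohort,
                          config = config$triage)

  report <- list(
    config_hash = config_hash(config),
    detected_patients = list(total = count_detected_patients(det),
                             glioma = count_detected_patients(det, "glioma")),
    pathogenic_ccfdna_patients =
      count_patients_tiered(tier2, "PATHOGENIC_CCFDNA_ONLY"),
    cohort_confirmed_patients =
      count_patients_tiered(tier34, c("COHORT_PRIOR_CONFIRMED",
                                      "COHORT_CURRENT_CONFIRMED",
                                      "CARRIER_BENIGN")),
    outputs = list(concordance = det, concordance_report =
                     emit_concordance_report(det),
                   pathogenic = tier2, cohort_confirmed = tier34))
  class(report) <- "run_report"
  report
}

#' @export
print.run_report <- function(x, ...) {
  cat("plasmatriage run report (config ", x$config_hash, ")\n", sep = "")
  for (s in names(x$stages)) {
    st <- x$stages[[s]]
    cat(sprintf("  %-8s input %5d  retained %5d  discarded %5d\n",
                s, st$input, st$retained, st$discarded))
  }
  if (!is.null(x$detected_patients))
    cat("  ctDNA-positive patients:", x$detected_patients$total,
        "(glioma:", x$detected_patients$glioma, ")\n")
  if (!is.null(x$pathogenic_ccfdna_patients))
    cat("  pathogenic plasma-only patients:",
        x$pathogenic_ccfdna_patients, "\n")
  if (!is.null(x$cohort_confirmed_patients))
    cat("  cohort-confirmed plasma patients:",
        x$cohort_confirmed_patients, "\n")
  invisible(x)
}
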