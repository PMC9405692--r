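# run expr with a local, restored RNG state; every sampling call in the
# package threads an explicit seed through this (no global state leaks)
with_seed <- function(seed, expr) {
  if (exists(".Random.seed", envir = globalenv())) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()))
  } else {
    on.exit(rm(".Random.seed", envir = globalenv()), add = TRUE)
  }
  set.seed(seed)
  force(expr)
}

#' Specification of a synthetic matched-trio cohort
#'
#' Defines the statistical structure the pipeline assumes: each patient
#' contributes germline heterozygous sites (allele fraction 0.5 in all
#' three compartments), clonal tumor somatic sites (tumor allele fraction
#' drawn from `somatic_af_range`), and plasma counts mixing ctDNA signal
#' at the patient's ctDNA fraction with per-read sequencing error. Alt
#' counts are Binomial(depth, p) with p the linear mixture
#' `f * af + (1 - f) * error_rate` at somatic sites in plasma. Depths are
#' the per-compartment panel means in `depth_model` (deterministic
#' coverage; coverage variation is not part of the model).
#'
#' @param n_patients number of patients.
#' @param diagnoses data frame with `label` and `proportion` (summing
#'   to 1). The default mirrors a brain-tumor cohort: mostly WHO grade 4
#'   glioma, some grade 3, plus PCNSL and metastatic patients.
#' @param panel panel data frame from [default_panel()].
#' @param seed integer base seed; patient `i` uses `seed + i`.
#' @param germline_het_sites_per_patient,somatic_sites_per_patient site
#'   counts per patient.
#' @param somatic_af_range clonal tumor allele-fraction interval.
#' @param ctdna_fraction_range interval the patient ctDNA fraction is
#'   drawn from (uniform).
#' @param error_rate per-read substitution probability.
#' @param depth_model named numeric: mean depth for `gdna`, `tdna`,
#'   `ccfdna`.
#' @param umi_duplicates PCR duplicate reads per plasma UMI family.
#' @return validated list of class `cohort_spec`.
#' @export
cohort_spec <- function(n_patients = 84,
                        diagnoses = data.frame(
                          label = c("Glioblastoma, Grade 4",
                                    "Astrocytoma Anaplasticum, Grade 3",
                                    "Primary Central Nervous System Lymphoma",
                                    "Anaplastic Thyroid Cancer Metastasis",
                                    "Adenocarcinoma Lung Metastasis"),
                          proportion = c(72, 8, 2, 1, 1) / 84,
                          stringsAsFactors = FALSE),
                        panel = default_panel(), seed = 1L,
                        germline_het_sites_per_patient = 20L,
                        somatic_sites_per_patient = 5L,
                        somatic_af_range = c(0.2, 0.7),
                        ctdna_fraction_range = c(0, 0.1),
                        error_rate = 1e-3,
                        depth_model = c(gdna = 200, tdna = 200, ccfdna = 2000),
                        umi_duplicates = 3L) {
  stopifnot(n_patients >= 1, nrow(panel) >= 1,
            abs(sum(diagnoses$proportion) - 1) < 1e-8,
            all(diagnoses$proportion >= 0),
            error_rate >= 0, error_rate <= 1,
            all(somatic_af_range >= 0), all(somatic_af_range <= 1),
            somatic_af_range[1] <= somatic_af_range[2],
            all(ctdna_fraction_range >= 0), all(ctdna_fraction_range <= 1),
            ctdna_fraction_range[1] <= ctdna_fraction_range[2],
            all(c("gdna", "tdna", "ccfdna") %in% names(depth_model)),
            umi_duplicates >= 1)
  if (any(depth_model <= 0)) stop("depth_model entries must be > 0")
  structure(as.list(environment()), class = "cohort_spec")
}

#' Simulate one patient's matched trio
#'
#' Draws the patient's diagnosis (deterministic allocation along the
#' cohort proportions), ctDNA fraction, germline heterozygous sites and
#' clonal tumor somatic sites, then per-compartment alt counts:
#' germline sites at rate 0.5 everywhere; somatic sites at the clonal AF
#' in tumor, `error_rate` in germline, and the ctDNA mixture rate in
#' plasma (raw read-level counts; see [simulate_umi_reads()] for the
#' molecule-level view the UMI collapse consumes).
#'
#' @param spec a [cohort_spec()].
#' @param patient_index patient number in `1:n_patients`.
#' @return list of class `simulated_trio`: `patient_id`, `diagnosis`,
#'   `ctdna_fraction`, `records` (one row per site with counts and truth
#'   labels), `fragment_profile`.
#' @export
simulate_trio <- function(spec, patient_index) {
  stopifnot(inherits(spec, "cohort_spec"),
            patient_index >= 1, patient_index <= spec$n_patients)
  with_seed(spec$seed + patient_index, {
    cum <- cumsum(spec$diagnoses$proportion)
    diagnosis <- spec$diagnoses$label[
      findInterval((patient_index - 0.5) / spec$n_patients, c(0, cum),
                   rightmost.closed = TRUE)]
    f <- stats::runif(1, spec$ctdna_fraction_range[1],
                      spec$ctdna_fraction_range[2])
    pos_all <- panel_positions(spec$panel)
    n_g <- spec$germline_het_sites_per_patient
    n_s <- spec$somatic_sites_per_patient
    take <- sample.int(nrow(pos_all), n_g + n_s)
    sites <- pos_all[take, , drop = FALSE]
    label <- c(rep("germline", n_g), rep("somatic", n_s))
    bases <- c("A", "C", "G", "T")
    ref <- sample(bases, n_g + n_s, replace = TRUE)
    alt <- vapply(ref, function(r) sample(setdiff(bases, r), 1), "")
    af_tum <- ifelse(label == "somatic",
                     stats::runif(n_g + n_s, spec$somatic_af_range[1],
                                  spec$somatic_af_range[2]), 0.5)
    e <- spec$error_rate
    p_g <- ifelse(label == "germline", 0.5, e)
    p_t <- af_tum
    p_c <- ifelse(label == "germline", 0.5, f * af_tum + (1 - f) * e)
    dm <- spec$depth_model
    records <- data.frame(
      patient = as.character(patient_index),
      chrom = sites$chrom, pos = sites$pos, gene = sites$gene,
      ref = ref, alt = alt, label = label,
      true_af_tumor = ifelse(label == "somatic", af_tum, NA_real_),
      true_ctdna_fraction = f,
      gdna_depth = dm[["gdna"]],
      gdna_alt = stats::rbinom(n_g + n_s, dm[["gdna"]], p_g),
      tumor_depth = dm[["tdna"]],
      tumor_alt = stats::rbinom(n_g + n_s, dm[["tdna"]], p_t),
      ccf_depth = dm[["ccfdna"]],
      ccf_alt = stats::rbinom(n_g + n_s, dm[["ccfdna"]], p_c),
      stringsAsFactors = FALSE)
    records <- records[order(records$chrom, records$pos), , drop = FALSE]
    rownames(records) <- NULL
    profile <- simulate_fragment_profile(fragment_length_model(),
                                         n_fragments = 2000,
                                         seed = spec$seed + patient_index)
    structure(list(patient_id = as.character(patient_index),
                   diagnosis = diagnosis, ctdna_fraction = f,
                   records = records, fragment_profile = profile),
              class = "simulated_trio")
  })
}

#' Simulate a whole cohort
#'
#' @param spec a [cohort_spec()].
#' @return list of class `simulated_cohort`: `spec`, `trios` (list of
#'   [simulate_trio()] results), and `truth` (stacked per-site truth
#'   table).
#' @export
simulate_cohort <- function(spec = cohort_spec()) {
  trios <- lapply(seq_len(spec$n_patients), function(i) simulate_trio(spec, i))
  truth <- do.call(rbind, lapply(trios, function(tr)
    cbind(tr$records[c("patient", "chrom", "pos", "ref", "alt", "label",
                       "true_af_tumor", "true_ctdna_fraction")],
          diagnosis = tr$diagnosis)))
  rownames(truth) <- NULL
  structure(list(spec = spec, trios = trios, truth = truth),
            class = "simulated_cohort")
}

#' Simulate UMI read families for a plasma site
#'
#' Molecule-level view of the plasma compartment: `n_families` original
#' molecules carry the alt allele either in a fixed number
#' (`alt_molecules`) or independently with probability `alt_fraction`
#' (the molecule-level signal, `ctdna_fraction * tumor_af` at a somatic
#' site). Each molecule is amplified into `duplicates` PCR duplicate reads
#' sharing one UMI tag; each read misreports its molecule's allele with
#' probability `duplicate_error`, so majority-vote collapsing is
#' non-trivial.
#'
#' @param n_families number of original molecules (consensus depth).
#' @param alt_fraction per-molecule alt probability (ignored when
#'   `alt_molecules` given).
#' @param alt_molecules exact number of alt molecules.
#' @param duplicates PCR duplicate reads per family (integer >= 1).
#' @param duplicate_error per-read substitution probability.
#' @param seed RNG seed.
#' @return data frame with one row per read: `umi`, `true_allele`,
#'   `allele`.
#' @export
simulate_umi_reads <- function(n_families, alt_fraction = 0,
                               alt_molecules = NULL, duplicates = 3L,
                               duplicate_error = 0, seed = 1L) {
  stopifnot(n_families >= 0, duplicates >= 1,
            duplicate_error >= 0, duplicate_error <= 1)
  with_seed(seed, {
    n_alt <- if (!is.null(alt_molecules)) alt_molecules
             else stats::rbinom(1, n_families, alt_fraction)
    stopifnot(n_alt <= n_families)
    true_allele <- rep(c("alt", "ref"), c(n_alt, n_families - n_alt))
    umi <- sprintf("umi%06d", seq_len(n_families))
    reads <- data.frame(
      umi = rep(umi, each = duplicates),
      true_allele = rep(true_allele, each = duplicates),
      stringsAsFactors = FALSE)
    flip <- stats::runif(nrow(reads)) < duplicate_error
    reads$allele <- ifelse(xor(reads$true_allele == "alt", flip), "alt", "ref")
    reads
  })
}

#' Fragment-length mixture model for ccfDNA
#'
#' Categorical mixture over the three nucleosomal peaks (mononucleosome at
#' 167 bp, di- and trinucleosome multiples) plus an optional long genomic
#' contaminant peak. Peak widths are Gaussian.
#'
#' @param mono_peak_bp mononucleosome peak (default 167 bp).
#' @param mono_range_bp nominal mononucleosome range (120-220 bp); the
#'   Gaussian sd is a sixth of its width.
#' @param dimer_weight,trimer_weight,contaminant_weight mixture weights;
#'   the mononucleosome takes the remainder (weights must sum to <= 1).
#' @param long_contaminant_bp contaminant peak position (default 2500 bp,
#'   i.e. the ">2000 bp" genomic fraction).
#' @return named list.
#' @export
fragment_length_model <- function(mono_peak_bp = 167,
                                  mono_range_bp = c(120, 220),
                                  dimer_weight = 0.15, trimer_weight = 0.05,
                                  contaminant_weight = 0,
                                  long_contaminant_bp = 2500) {
  w <- c(dimer_weight, trimer_weight, contaminant_weight)
  stopifnot(all(w >= 0), sum(w) <= 1, mono_peak_bp > 0,
            long_contaminant_bp > 2000)
  list(mono_peak_bp = mono_peak_bp, mono_range_bp = mono_range_bp,
       weights = c(mono = 1 - sum(w), dimer = dimer_weight,
                   trimer = trimer_weight, contaminant = contaminant_weight),
       long_contaminant_bp = long_contaminant_bp)
}

#' Sample a fragment-length histogram
#'
#' @param model a [fragment_length_model()].
#' @param n_fragments number of fragments to draw (> 0).
#' @param seed RNG seed.
#' @return data frame `length_bp` / `abundance` (fragment counts).
#' @export
simulate_fragment_profile <- function(model = fragment_length_model(),
                                      n_fragments = 1e4, seed = 1L) {
  stopifnot(n_fragments > 0)
  with_seed(seed, {
    sd_mono <- diff(model$mono_range_bp) / 6
    comp <- sample(names(model$weights), n_fragments, replace = TRUE,
                   prob = model$weights)
    mu <- c(mono = model$mono_peak_bp, dimer = 2 * model$mono_peak_bp,
            trimer = 3 * model$mono_peak_bp,
            contaminant = model$long_contaminant_bp)[comp]
    sdv <- c(mono = sd_mono, dimer = 1.5 * sd_mono, trimer = 2 * sd_mono,
             contaminant = 100)[comp]
    len <- pmax(30L, as.integer(round(stats::rnorm(n_fragments, mu, sdv))))
    tab <- table(len)
    data.frame(length_bp = as.integer(names(tab)),
               abundance = as.integer(tab))
  })
}

#' Write a simulated cohort to disk
#'
#' One minimal VCF v4.2 per patient with FORMAT fields `DP` (depth) and
#' `AD` (ref,alt) over three sample columns (`gDNA`, `tDNA`, `ccfDNA`;
#' 1-based positions), plus a cohort-level truth table TSV. Output
#' ordering is deterministic, so identical cohorts serialize to identical
#' bytes.
#'
#' @param cohort a [simulate_cohort()] result.
#' @param out_dir output directory (created if missing).
#' @return invisibly, the written file paths.
#' @export
write_cohort <- function(cohort, out_dir) {
  stopifnot(inherits(cohort, "simulated_cohort"))
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  paths <- character()
  contigs <- unique(cohort$spec$panel$chrom)
  for (tr in cohort$trios) {
    r <- tr$records
    header <- c("##fileformat=VCFv4.2",
                "##source=plasmatriage_synthetic_cohort",
                paste0("##contig=<ID=", contigs, ">"),
                "##FORMAT=<ID=DP,Number=1,Type=Integer,Description=\"Read depth\">",
                "##FORMAT=<ID=AD,Number=R,Type=Integer,Description=\"Ref,alt read depths\">",
                paste("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER",
                      "INFO", "FORMAT", "gDNA", "tDNA", "ccfDNA", sep = "\t"))
    fmt <- function(depth, alt) paste0(depth, ":", depth - alt, ",", alt)
    body <- paste(r$chrom, r$pos, ".", r$ref, r$alt, ".", "PASS", ".",
                  "DP:AD",
                  fmt(r$gdna_depth, r$gdna_alt),
                  fmt(r$tumor_depth, r$tumor_alt),
                  fmt(r$ccf_depth, r$ccf_alt), sep = "\t")
    path <- file.path(out_dir, sprintf("patient%s.vcf", tr$patient_id))
    writeLines(c(header, body), path)
    paths <- c(paths, path)
  }
  truth_path <- file.path(out_dir, "truth.tsv")
  utils::write.table(cohort$truth, truth_path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(c(paths, truth_path))
}

#' Read trio counts back from a cohort directory
#'
#' Parses the per-patient VCFs written by [write_cohort()] (via `vcfR`)
#' back into the stacked trio count table.
#'
#' @param dir directory written by [write_cohort()].
#' @return data frame with `patient`, `chrom`, `pos`, `ref`, `alt` and the
#'   six per-compartment count columns.
#' @export
read_cohort <- function(dir) {
  files <- sort(list.files(dir, pattern = "^patient.*\\.vcf$",
                           full.names = TRUE))
  if (length(files) == 0) stop("no patient VCFs under ", dir)
  one <- function(path) {
    v <- vcfR::read.vcfR(path, verbose = FALSE)
    dp <- vcfR::extract.gt(v, "DP", as.numeric = TRUE)
    ad <- vcfR::extract.gt(v, "AD")
    alt_of <- function(col) as.integer(sub("^[0-9]+,", "", ad[, col]))
    fix <- as.data.frame(vcfR::getFIX(v), stringsAsFactors = FALSE)
    data.frame(patient = sub("^patient(.*)\\.vcf$", "\\1", basename(path)),
               chrom = fix$CHROM, pos = as.integer(fix$POS),
               ref = fix$REF, alt = fix$ALT,
               gdna_depth = dp[, "gDNA"], gdna_alt = alt_of("gDNA"),
               tumor_depth = dp[, "tDNA"], tumor_alt = alt_of("tDNA"),
               ccf_depth = dp[, "ccfDNA"], ccf_alt = alt_of("ccfDNA"),
               stringsAsFactors = FALSE)
  }
  out <- do.call(rbind, lapply(files, one))
  rownames(out) <- NULL
  out
}
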