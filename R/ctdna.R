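#' ctDNA detection configuration
#'
#' @param min_plasma_alt minimum alt-supporting plasma consensus reads for
#'   a tumor-somatic variant to count as detected in ccfDNA. Default 3,
#'   mirroring the tumor-side "at least 3 reads" rule; there is no plasma
#'   AF floor by default (concordant variants down to AF 0.009 are real).
#' @param min_plasma_af optional minimum plasma allele frequency (0 = off).
#' @return named list.
#' @export
detection_config <- function(min_plasma_alt = 3, min_plasma_af = 0) {
  stopifnot(min_plasma_alt >= 0, min_plasma_af >= 0, min_plasma_af <= 1)
  list(min_plasma_alt = min_plasma_alt, min_plasma_af = min_plasma_af)
}

#' Collapse UMI read families to consensus counts
#'
#' Groups plasma reads by UMI tag and takes the family-majority allele as
#' the consensus for each original molecule. Families whose vote ties are
#' ambiguous and excluded (base qualities are out of scope, so no
#' quality-weighted tie-break). Consensus depth is the number of
#' unambiguous families; consensus alt is the number whose majority allele
#' is the alt allele.
#'
#' @param reads data frame with columns `umi` (family tag) and `allele`
#'   (`"ref"` or `"alt"` observation per read). An optional `site` column
#'   restricts grouping within sites; counts are returned per site.
#' @return data frame with `site` (if supplied), `depth` (unambiguous
#'   families), `alt` (alt-consensus families), `n_ambiguous`,
#'   `n_reads`.
#' @export
collapse_umi <- function(reads) {
  stopifnot(all(c("umi", "allele") %in% names(reads)),
            all(reads$allele %in% c("ref", "alt")))
  site <- if (is.null(reads$site)) rep("site1", nrow(reads)) else reads$site
  per_site <- lapply(split(reads, site), function(r) {
    alt_per_fam <- tapply(r$allele == "alt", r$umi, sum)
    size <- tapply(r$allele, r$umi, length)
    maj_alt <- alt_per_fam * 2 > size
    tie <- alt_per_fam * 2 == size
    data.frame(depth = sum(!tie), alt = sum(maj_alt & !tie),
               n_ambiguous = sum(tie), n_reads = nrow(r))
  })
  out <- do.call(rbind, per_site)
  out <- cbind(site = names(per_site), out, stringsAsFactors = FALSE)
  rownames(out) <- NULL
  if (is.null(reads$site)) out$site <- NULL
  out
}

#' Test tumor-somatic variants for presence in plasma
#'
#' The concordance rule: a variant already classified somatic in the
#' matched tumor is detected in ccfDNA when its plasma consensus counts
#' carry at least `min_plasma_alt` alt reads (and at least `min_plasma_af`
#' allele frequency, off by default). Plasma depth 0 is reported as not
#' detected with reason `no_coverage`.
#'
#' @param trios data frame with one row per tumor-somatic variant and
#'   numeric columns `ccf_depth`, `ccf_alt` (plasma consensus counts); all
#'   other columns (patient, gene, diagnosis, tumor/gDNA counts) are
#'   carried through.
#' @param config a [detection_config()].
#' @return `trios` with added `ccf_af` (numeric), `detected` (logical) and
#'   `detect_reason`.
#' @export
detect_ctdna <- function(trios, config = detection_config()) {
  af <- allele_frequency(trios$ccf_alt, trios$ccf_depth)
  no_cov <- trios$ccf_depth == 0
  detected <- !no_cov & trios$ccf_alt >= config$min_plasma_alt &
    (config$min_plasma_af == 0 | (!is.na(af) & af >= config$min_plasma_af))
  trios$ccf_af_value <- af
  trios$detected <- detected
  trios$detect_reason <- ifelse(no_cov, "no_coverage",
                                ifelse(detected, "detected",
                                       "below_min_plasma_alt"))
  trios
}

#' Concordance report table
#'
#' One row per detected variant with the three compartments' counts and
#' allele frequencies, plasma AF at 3 decimals as in the printed report.
#'
#' @param calls output of [detect_ctdna()].
#' @return data frame of detected rows (header-only when none).
#' @export
emit_concordance_report <- function(calls) {
  det <- calls[calls$detected, , drop = FALSE]
  cols <- intersect(c("gene", "chrom", "pos", "patient", "ref", "alt",
                      "diagnosis", "gdna_depth", "gdna_alt",
                      "tumor_depth", "tumor_alt", "ccf_depth", "ccf_alt"),
                    names(det))
  out <- det[, cols, drop = FALSE]
  if (!is.null(det$gdna_depth))
    out$gdna_af <- format_af(allele_frequency(det$gdna_alt, det$gdna_depth), 2)
  if (!is.null(det$tumor_depth))
    out$tumor_af <- format_af(allele_frequency(det$tumor_alt, det$tumor_depth), 2)
  out$ccf_af <- format_af(det$ccf_af_value, 3)
  rownames(out) <- NULL
  out
}

#' Count patients with detected ctDNA
#'
#' Distinct patients with at least one detected variant, optionally
#' restricted to a diagnosis class from [classify_diagnosis()] (for the
#' glioma subgroup count, PCNSL and metastases are excluded).
#'
#' @param calls output of [detect_ctdna()].
#' @param diagnosis_class optional class filter (e.g. `"glioma"`).
#' @return integer patient count.
#' @export
count_detected_patients <- function(calls, diagnosis_class = NULL) {
  det <- calls[calls$detected, , drop = FALSE]
  if (!is.null(diagnosis_class))
    det <- det[classify_diagnosis(det$diagnosis) %in% diagnosis_class, ,
               drop = FALSE]
  length(unique(det$patient))
}
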