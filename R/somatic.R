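#' Somatic-calling filter configuration
#'
#' Thresholds of the tumor/germline calling stage. The defaults are the
#' literal retention rules of the pipeline: site coverage of at least 10
#' reads, at least 3 alt reads and at least 1% allele frequency in the
#' tumor, less than 1% allele frequency in the germline. Boundary semantics
#' are inclusive/exclusive exactly as stated ("at least" is `>=`,
#' "less than" is `<`).
#'
#' @param min_coverage minimum tumor read depth at the site.
#' @param min_alt_tumor minimum alt-supporting tumor reads.
#' @param min_tumor_af minimum tumor allele frequency (inclusive).
#' @param max_gdna_af germline allele frequency must be strictly below this.
#' @param fisher_p_max significance cutoff on the tumor-vs-germline Fisher
#'   exact p-value for somatic status.
#' @param strand_bias_p p-value cutoff of the strand x allele Fisher test.
#' @param strand_bias_min_skew minimum fraction of alt reads on one strand
#'   for a call to count as strand-biased (both conditions must hold).
#' @param sift_damaging_max SIFT score below which a variant is predicted
#'   damaging (standard convention).
#' @param sift_damaging_is_high set `TRUE` to invert the SIFT convention
#'   (treat scores above `sift_damaging_max` as damaging).
#' @param population_af_max catalog variants with population allele
#'   frequency above this are treated as common polymorphisms and dropped.
#' @param loh_band germline heterozygous band used for LOH classification.
#' @return a named list of class `filter_config`.
#' @export
filter_config <- function(min_coverage = 10, min_alt_tumor = 3,
                          min_tumor_af = 0.01, max_gdna_af = 0.01,
                          fisher_p_max = 0.05,
                          strand_bias_p = 0.05, strand_bias_min_skew = 0.9,
                          sift_damaging_max = 0.05,
                          sift_damaging_is_high = FALSE,
                          population_af_max = 0.001,
                          loh_band = c(0.25, 0.75)) {
  stopifnot(min_coverage >= 0, min_alt_tumor >= 0,
            min_tumor_af >= 0, min_tumor_af <= 1,
            max_gdna_af >= 0, max_gdna_af <= 1,
            fisher_p_max > 0, fisher_p_max <= 1,
            strand_bias_min_skew >= 0.5, strand_bias_min_skew <= 1,
            length(loh_band) == 2, loh_band[1] < loh_band[2])
  structure(as.list(environment()), class = "filter_config")
}

#' Two-sided Fisher exact test for a 2x2 count table
#'
#' Conditional hypergeometric test on the table (alt, ref) x (group a,
#' group b). The two-sided p-value is the sum of probabilities of all
#' tables with the observed margins whose probability does not exceed the
#' observed table's (with the conventional relative tolerance of 1e-7 for
#' ties). An all-zero table has p = 1.
#'
#' Vectorized over sites; used both for the tumor-vs-germline somatic test
#' and, with strands as groups, for the strand-bias filter.
#'
#' @param alt_a,ref_a alt/ref counts in the first group (e.g. tumor).
#' @param alt_b,ref_b alt/ref counts in the second group (e.g. germline).
#' @return numeric vector of two-sided p-values.
#' @export
#' @examples
#' fisher_exact_2x2(5, 5, 5, 5)        # identical margins -> 1
#' fisher_exact_2x2(144, 5, 0, 106)    # Table-1-scale somatic site
fisher_exact_2x2 <- function(alt_a, ref_a, alt_b, ref_b) {
  n <- max(length(alt_a), length(ref_a), length(alt_b), length(ref_b))
  alt_a <- rep_len(alt_a, n); ref_a <- rep_len(ref_a, n)
  alt_b <- rep_len(alt_b, n); ref_b <- rep_len(ref_b, n)
  stopifnot(all(c(alt_a, ref_a, alt_b, ref_b) >= 0))
  one <- function(aa, ra, ab, rb) {
    m <- aa + ra          # group-a margin
    nn <- ab + rb         # group-b margin
    k <- aa + ab          # alt margin
    if (k == 0 || k == m + nn || m == 0 || nn == 0) return(1)
    support <- max(0, k - nn):min(k, m)
    d <- stats::dhyper(support, m, nn, k)
    d_obs <- stats::dhyper(aa, m, nn, k)
    sum(d[d <= d_obs * (1 + 1e-7)])
  }
  mapply(one, alt_a, ref_a, alt_b, ref_b)
}

#' Strand-bias test for a call
#'
#' Fisher exact test on the strand x allele table, combined with an
#' alt-strand skew requirement: a call is flagged strand-biased when the
#' test is significant at `config$strand_bias_p` *and* at least
#' `config$strand_bias_min_skew` of the alt reads sit on a single strand.
#' Sites without strand information are never flagged.
#'
#' @param alt_fwd,alt_rev per-strand alt read counts.
#' @param ref_fwd,ref_rev per-strand ref read counts.
#' @param config a [filter_config()].
#' @return logical vector, `TRUE` where the call is strand-biased.
#' @export
strand_bias_test <- function(alt_fwd, alt_rev, ref_fwd, ref_rev,
                             config = filter_config()) {
  n <- max(length(alt_fwd), length(alt_rev), length(ref_fwd), length(ref_rev))
  alt_fwd <- rep_len(alt_fwd, n); alt_rev <- rep_len(alt_rev, n)
  ref_fwd <- rep_len(ref_fwd, n); ref_rev <- rep_len(ref_rev, n)
  has_info <- !(is.na(alt_fwd) | is.na(alt_rev) | is.na(ref_fwd) | is.na(ref_rev))
  biased <- rep(FALSE, n)
  if (any(has_info)) {
    p <- fisher_exact_2x2(alt_fwd[has_info], alt_rev[has_info],
                          ref_fwd[has_info], ref_rev[has_info])
    alt_tot <- alt_fwd[has_info] + alt_rev[has_info]
    skew <- ifelse(alt_tot > 0,
                   pmax(alt_fwd[has_info], alt_rev[has_info]) / alt_tot, 0)
    biased[has_info] <- p < config$strand_bias_p &
      skew >= config$strand_bias_min_skew
  }
  biased
}

#' Classify sites as somatic / germline / LOH / unknown
#'
#' Tumor-vs-germline classification of candidate variant sites from read
#' counts, in the spirit of VarScan2's high-confidence somatic extraction:
#' a site is `somatic` when the Fisher exact p-value is significant, the
#' germline allele frequency is below `max_gdna_af` and the tumor allele
#' frequency reaches `min_tumor_af`; `LOH` when the germline is
#' heterozygous (AF within `loh_band`) and the tumor AF leaves the band
#' with a significant p-value; `germline` when both compartments carry the
#' allele at heterozygous-or-higher frequency; otherwise `unknown`.
#'
#' @param tumor,germline data frames (or lists) with numeric fields `depth`
#'   and `alt`, one entry per site; tumor may also carry `alt_fwd`,
#'   `alt_rev`, `ref_fwd`, `ref_rev` strand counts used later by
#'   [apply_retention_filters()].
#' @param config a [filter_config()].
#' @return data frame with per-site `tumor_depth`, `tumor_alt`, `tumor_af`,
#'   `gdna_depth`, `gdna_alt`, `gdna_af`, `fisher_p`, `status` and the
#'   strand columns when supplied.
#' @export
classify_site <- function(tumor, germline, config = filter_config()) {
  tumor <- as.data.frame(tumor); germline <- as.data.frame(germline)
  stopifnot(nrow(tumor) == nrow(germline),
            all(tumor$alt <= tumor$depth), all(germline$alt <= germline$depth))
  af_t <- allele_frequency(tumor$alt, tumor$depth)
  af_g <- allele_frequency(germline$alt, germline$depth)
  p <- fisher_exact_2x2(tumor$alt, tumor$depth - tumor$alt,
                        germline$alt, germline$depth - germline$alt)
  band <- config$loh_band
  somatic <- !is.na(af_t) & !is.na(af_g) &
    p <= config$fisher_p_max & af_g < config$max_gdna_af &
    af_t >= config$min_tumor_af
  het_g <- !is.na(af_g) & af_g >= band[1] & af_g <= band[2]
  loh <- !somatic & het_g & !is.na(af_t) &
    (af_t < band[1] | af_t > band[2]) & p <= config$fisher_p_max
  germ <- !somatic & !loh & !is.na(af_g) & !is.na(af_t) &
    af_g >= band[1] & af_t >= band[1]
  status <- ifelse(somatic, "somatic",
                   ifelse(loh, "LOH", ifelse(germ, "germline", "unknown")))
  out <- data.frame(tumor_depth = tumor$depth, tumor_alt = tumor$alt,
                    tumor_af = af_t,
                    gdna_depth = germline$depth, gdna_alt = germline$alt,
                    gdna_af = af_g,
                    fisher_p = p, status = status,
                    stringsAsFactors = FALSE)
  for (col in c("alt_fwd", "alt_rev", "ref_fwd", "ref_rev"))
    if (!is.null(tumor[[col]])) out[[col]] <- tumor[[col]]
  out
}

#' Apply the literal retention thresholds to classified calls
#'
#' Drops calls with tumor coverage below `min_coverage`, fewer than
#' `min_alt_tumor` alt reads, tumor AF below `min_tumor_af`, germline AF at
#' or above `max_gdna_af`, or strand-supporting-read bias. Every call keeps
#' a `reasons` trail naming each failed rule; `retained` is `TRUE` only for
#' somatic-status calls passing every rule, so that
#' `sum(retained) + sum(!retained) == nrow(input)`.
#'
#' @param calls data frame from [classify_site()] (any extra columns are
#'   carried through).
#' @param config a [filter_config()].
#' @return `calls` with added `retained` (logical) and `reasons`
#'   (semicolon-separated rule names, empty when retained).
#' @export
apply_retention_filters <- function(calls, config = filter_config()) {
  n <- nrow(calls)
  fail <- list(
    status_not_somatic = calls$status != "somatic",
    min_coverage = calls$tumor_depth < config$min_coverage,
    min_alt_tumor = calls$tumor_alt < config$min_alt_tumor,
    min_tumor_af = is.na(calls$tumor_af) | calls$tumor_af < config$min_tumor_af,
    max_gdna_af = is.na(calls$gdna_af) | calls$gdna_af >= config$max_gdna_af
  )
  if (!is.null(calls$alt_fwd)) {
    fail$strand_bias <- strand_bias_test(calls$alt_fwd, calls$alt_rev,
                                         calls$ref_fwd, calls$ref_rev, config)
  }
  fail_m <- do.call(cbind, fail)
  calls$retained <- rowSums(fail_m, na.rm = TRUE) == 0
  calls$reasons <- apply(fail_m, 1, function(f)
    paste(names(fail)[which(f)], collapse = ";"))
  calls
}

#' Population-frequency and predicted-effect filters
#'
#' Removes retained calls that are common population polymorphisms
#' (annotation population AF above `population_af_max` in any of MAF,
#' 1000 Genomes or gnomAD), non-coding calls (when the catalog carries a
#' `coding` column), and calls whose SIFT score predicts a tolerated
#' change. Variants absent from the catalog are kept: absence from
#' population databases is evidence of rarity, and missing SIFT scores are
#' not treated as benign.
#'
#' @param calls data frame with a `key` column ([variant_key()]) and a
#'   `retained` column (from [apply_retention_filters()]).
#' @param annotation catalog data frame with `key` and any of `maf`,
#'   `af_1000g`, `af_gnomad`, `clinsig`, `sift`, `coding`.
#' @param config a [filter_config()].
#' @return `calls` with `retained`/`reasons` updated.
#' @export
filter_population_and_effect <- function(calls, annotation,
                                         config = filter_config()) {
  idx <- match(calls$key, annotation$key)
  pick <- function(col) {
    v <- annotation[[col]]
    if (is.null(v)) rep(NA, nrow(calls)) else v[idx]
  }
  pop_af <- pmax(as.numeric(pick("maf")), as.numeric(pick("af_1000g")),
                 as.numeric(pick("af_gnomad")), 0, na.rm = TRUE)
  common <- pop_af > config$population_af_max
  coding <- pick("coding")
  noncoding <- !is.na(coding) & !as.logical(coding)
  sift <- as.numeric(pick("sift"))
  tolerated <- if (config$sift_damaging_is_high) {
    !is.na(sift) & sift <= config$sift_damaging_max
  } else {
    !is.na(sift) & sift >= config$sift_damaging_max
  }
  add_reason <- function(reasons, flag, label)
    ifelse(flag, ifelse(nzchar(reasons), paste(reasons, label, sep = ";"),
                        label), reasons)
  calls$reasons <- add_reason(calls$reasons, common, "population_common")
  calls$reasons <- add_reason(calls$reasons, noncoding, "non_coding")
  calls$reasons <- add_reason(calls$reasons, tolerated, "sift_tolerated")
  calls$retained <- calls$retained & !common & !noncoding & !tolerated
  calls
}

#' Per-gene mutated-patient counts
#'
#' @param calls data frame with `gene` and `patient` columns; only rows
#'   with `retained == TRUE` are counted when the column is present.
#' @return data frame (gene, n_patients, rank), descending by count; ties
#'   share the minimum rank.
#' @export
summarize_gene_frequencies <- function(calls) {
  if (!is.null(calls$retained)) calls <- calls[calls$retained, , drop = FALSE]
  if (nrow(calls) == 0)
    return(data.frame(gene = character(), n_patients = integer(),
                      rank = integer(), stringsAsFactors = FALSE))
  tab <- stats::aggregate(patient ~ gene, data = calls,
                          FUN = function(p) length(unique(p)))
  names(tab)[2] <- "n_patients"
  tab <- tab[order(-tab$n_patients, tab$gene), , drop = FALSE]
  tab$rank <- rank(-tab$n_patients, ties.method = "min")
  rownames(tab) <- NULL
  tab
}

#' Per-gene tumor-VAF distributions
#'
#' @param calls data frame with `gene` and `tumor_af`; rows with missing AF
#'   are dropped. Only retained calls are summarized when a `retained`
#'   column is present.
#' @return named list: one sorted numeric vector of VAFs per gene. Genes
#'   without calls are absent.
#' @export
vaf_by_gene <- function(calls) {
  if (!is.null(calls$retained)) calls <- calls[calls$retained, , drop = FALSE]
  calls <- calls[!is.na(calls$tumor_af), , drop = FALSE]
  if (nrow(calls) == 0) return(structure(list(), names = character()))
  lapply(split(calls$tumor_af, calls$gene), sort)
}
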