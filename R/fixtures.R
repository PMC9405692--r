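#' Packaged report-table fixtures
#'
#' The package ships four small TSV fixtures transcribed from the printed
#' result tables of the brain-tumor liquid-biopsy study it implements: the
#' tumor/plasma concordance table (17 variant rows), the COSMIC-registered
#' plasma-only variant table (36 rows with annotation columns), and the two
#' cohort-confirmation tables (13 prior-cohort rows, 8 current-cohort rows).
#' They stand in for the controlled-access raw sequencing data and are the
#' reproduction surface for the study's headline patient counts.
#'
#' Each row carries per-compartment read counts (`*_depth`, `*_alt`) plus
#' the allele-frequency cell exactly as printed (`*_af`), so that every AF
#' can be recomputed as alt/depth and checked at the printed precision.
#'
#' @return a list of data frames: `concordance`, `ccfdna_only`,
#'   `prior_cohort`, `current_cohort`. A basic row/column integrity check is
#'   applied at load time.
#' @export
load_fixture_tables <- function() {
  read_fix <- function(name, nrow_expect) {
    path <- system.file("extdata", name, package = "plasmatriage")
    if (!nzchar(path)) stop("fixture not found: ", name)
    x <- utils::read.delim(path, stringsAsFactors = FALSE,
                           colClasses = "character")
    if (nrow(x) != nrow_expect)
      stop("fixture ", name, ": expected ", nrow_expect, " rows, got ", nrow(x))
    x
  }
  fix <- list(
    concordance    = read_fix("table1_concordance.tsv",    17L),
    ccfdna_only    = read_fix("table2_ccfdna_only.tsv",    36L),
    prior_cohort   = read_fix("table3_prior_cohort.tsv",   13L),
    current_cohort = read_fix("table4_current_cohort.tsv",  8L)
  )
  num_cols <- function(df, cols) {
    df[cols] <- lapply(df[cols], as.numeric)
    df
  }
  fix$concordance <- num_cols(fix$concordance,
    c("pos", "gdna_depth", "gdna_alt", "tumor_depth", "tumor_alt",
      "ccf_depth", "ccf_alt"))
  fix$ccfdna_only <- num_cols(fix$ccfdna_only,
    c("pos", "maf", "af_1000g", "af_gnomad",
      "gdna_depth", "gdna_alt", "ccf_depth", "ccf_alt"))
  fix$prior_cohort <- num_cols(fix$prior_cohort,
    c("cosmic_cns_count", "gmaf", "gdna_depth", "gdna_alt",
      "ccf_depth", "ccf_alt", "tumor_af_other"))
  fix$current_cohort <- num_cols(fix$current_cohort,
    c("pos", "gdna_depth", "gdna_alt", "ccf_depth", "ccf_alt",
      "n_patients_somatic"))
  fix
}

#' Build annotation and cohort catalogs from the packaged fixtures
#'
#' Derives the three catalog inputs the triage stage consumes from the
#' fixture tables: an annotation catalog (rsID, population AFs, clinical
#' significance, COSMIC registration) and a cohort catalog of variant
#' identities confirmed somatic in the prior or the current cohort.
#'
#' @param fix result of [load_fixture_tables()].
#' @return list with data frames `annotation` (key, rsid, maf, af_1000g,
#'   af_gnomad, clinsig, cosmic_registered) and `cohort` (key, source,
#'   n_patients).
#' @export
fixture_catalogs <- function(fix = load_fixture_tables()) {
  t2 <- fix$ccfdna_only
  t3 <- fix$prior_cohort
  t4 <- fix$current_cohort
  ann <- rbind(
    data.frame(key = variant_key(t2$chrom, t2$pos, rsid = t2$rsid),
               rsid = t2$rsid, maf = t2$maf, af_1000g = t2$af_1000g,
               af_gnomad = t2$af_gnomad,
               clinsig = normalize_clinsig(t2$clinsig),
               # the plasma-only table is by construction COSMIC-registered
               cosmic_registered = TRUE,
               stringsAsFactors = FALSE),
    data.frame(key = variant_key(NA, NA, rsid = t3$rsid),
               rsid = t3$rsid, maf = t3$gmaf, af_1000g = NA_real_,
               af_gnomad = NA_real_,
               clinsig = normalize_clinsig(t3$clinsig),
               cosmic_registered = !is.na(t3$cosmic_cns_count) &
                 t3$cosmic_cns_count > 0,
               stringsAsFactors = FALSE),
    data.frame(key = variant_key(t4$chrom, t4$pos, t4$ref, t4$alt, t4$rsid),
               rsid = t4$rsid, maf = NA_real_, af_1000g = NA_real_,
               af_gnomad = NA_real_,
               clinsig = normalize_clinsig(t4$clinsig),
               cosmic_registered = t4$cosmic_registered == "yes",
               stringsAsFactors = FALSE)
  )
  ann <- ann[!duplicated(ann$key), ]
  cohort <- rbind(
    data.frame(key = variant_key(NA, NA, rsid = t3$rsid), source = "prior",
               n_patients = 1L, stringsAsFactors = FALSE),
    data.frame(key = variant_key(t4$chrom, t4$pos, t4$ref, t4$alt, t4$rsid),
               source = "current", n_patients = t4$n_patients_somatic,
               stringsAsFactors = FALSE)
  )
  cohort <- cohort[!duplicated(cohort[c("key", "source")]), ]
  list(annotation = ann, cohort = cohort)
}
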