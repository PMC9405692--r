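#' CNA caller configuration
#'
#' @param gain_threshold minimum exon log2 ratio for a gain call
#'   (default `log2(1.25)`, i.e. 2.5 copies or more against a diploid
#'   control).
#' @param loss_threshold maximum exon log2 ratio for a loss call
#'   (default -0.42, roughly 1.5 copies).
#' @param cosmic_genes character vector of registered cancer genes used to
#'   set the `cosmic_flag` on calls.
#' @return named list.
#' @export
cna_config <- function(gain_threshold = log2(1.25), loss_threshold = -0.42,
                       cosmic_genes = c("EGFR", "PDGFRA", "MDM2", "CDK4",
                                        "MET", "PIK3CA", "BRAF", "MTOR",
                                        "TP53", "PTEN", "CDKN2A", "NF1",
                                        "SMARCA4", "NOTCH1", "RB1")) {
  stopifnot(gain_threshold > 0, loss_threshold < 0)
  as.list(environment())
}

#' Normalize exon depths to panel-mean 1 per compartment
#'
#' Scales each depth column so its panel-wide mean is exactly 1,
#' preserving relative exon values; a prerequisite of any depth ratio.
#'
#' @param coverages data frame with exon rows and one or more depth
#'   columns (any column whose name starts with `depth_`).
#' @return `coverages` with the depth columns rescaled.
#' @export
normalize_depths <- function(coverages) {
  stopifnot(nrow(coverages) >= 1)
  cols <- grep("^depth_", names(coverages), value = TRUE)
  if (length(cols) == 0) stop("no depth_* columns to normalize")
  for (col in cols) {
    m <- mean(coverages[[col]])
    if (m == 0) stop("all-zero depth column: ", col)
    coverages[[col]] <- coverages[[col]] / m
  }
  coverages
}

#' Per-exon log2 depth ratio
#'
#' @param test,control normalized depth vectors (same length).
#' @return numeric log2(test/control); exons with control 0 are masked
#'   (`NA`) rather than infinite.
#' @export
exon_log2_ratio <- function(test, control) {
  stopifnot(length(test) == length(control))
  ifelse(control > 0, log2(test / control), NA_real_)
}

#' Threshold-and-merge copy-number calls from exon ratios
#'
#' Each exon is labelled `gain`, `loss` or `neutral` by the configured
#' log2-ratio thresholds; adjacent same-state exons within a gene are
#' merged into one call (run-length encoding; merging never changes an
#' exon's state). Masked exons (`NA` ratio) break runs and produce no
#' call. Copy estimate is `2 * 2^ratio` of the mean ratio over the merged
#' run.
#'
#' @param exons data frame with `chrom`, `start`, `end`, `gene`, `exon`.
#' @param ratios per-exon log2 ratios aligned with `exons`.
#' @param config a [cna_config()].
#' @param keep_neutral also emit neutral segments (default `FALSE`:
#'   only gain/loss calls are returned).
#' @return data frame of calls: `chrom`, `start`, `end`, `gene`,
#'   `n_exons`, `log2_ratio` (run mean), `copy_estimate`, `state`,
#'   `cosmic_flag`.
#' @export
call_states <- function(exons, ratios, config = cna_config(),
                        keep_neutral = FALSE) {
  stopifnot(nrow(exons) == length(ratios))
  state <- ifelse(is.na(ratios), NA_character_,
                  ifelse(ratios >= config$gain_threshold, "gain",
                         ifelse(ratios <= config$loss_threshold, "loss",
                                "neutral")))
  ord <- order(exons$gene, exons$chrom, exons$start)
  exons <- exons[ord, , drop = FALSE]
  ratios <- ratios[ord]; state <- state[ord]
  run_id <- cumsum(c(TRUE, exons$gene[-1] != exons$gene[-nrow(exons)] |
                       state[-1] != state[-length(state)] |
                       is.na(state[-1]) != is.na(state[-length(state)])))
  keep <- !is.na(state)
  calls <- lapply(split(which(keep), run_id[keep]), function(i) {
    data.frame(chrom = exons$chrom[i[1]], start = min(exons$start[i]),
               end = max(exons$end[i]), gene = exons$gene[i[1]],
               n_exons = length(i), log2_ratio = mean(ratios[i]),
               copy_estimate = 2 * 2^mean(ratios[i]),
               state = state[i[1]], stringsAsFactors = FALSE)
  })
  out <- if (length(calls)) do.call(rbind, calls) else
    data.frame(chrom = character(), start = integer(), end = integer(),
               gene = character(), n_exons = integer(),
               log2_ratio = numeric(), copy_estimate = numeric(),
               state = character(), stringsAsFactors = FALSE)
  if (!keep_neutral) out <- out[out$state != "neutral", , drop = FALSE]
  out$cosmic_flag <- out$gene %in% config$cosmic_genes
  out <- out[order(out$chrom, out$start), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Split copy-number calls into germline and somatic origin
#'
#' Germline calls come from the matched blood sample against a reference
#' normal; somatic calls from the test compartment (tumor or ccfDNA)
#' against the matched blood. A somatic call whose gene carries a
#' same-state germline call is reported with `origin = "germline"`
#' (inherited, not tumor-derived); the rest are `origin = "somatic"`.
#'
#' @param coverages data frame with exon columns and depths `depth_test`,
#'   `depth_matched`, `depth_reference`.
#' @param config a [cna_config()].
#' @return list with `germline` and `somatic` call data frames (the
#'   somatic table has the `origin` column).
#' @export
germline_vs_somatic_split <- function(coverages, config = cna_config()) {
  need <- c("depth_test", "depth_matched", "depth_reference")
  missing_tracks <- setdiff(need, names(coverages))
  if (length(missing_tracks) > 0)
    warning("missing coverage tracks: ",
            paste(missing_tracks, collapse = ", "), "; partial output")
  norm <- normalize_depths(coverages)
  exon_cols <- norm[c("chrom", "start", "end", "gene", "exon")]
  germline <- if (all(c("depth_matched", "depth_reference") %in% names(norm))) {
    call_states(exon_cols,
                exon_log2_ratio(norm$depth_matched, norm$depth_reference),
                config)
  } else NULL
  somatic <- if (all(c("depth_test", "depth_matched") %in% names(norm))) {
    call_states(exon_cols,
                exon_log2_ratio(norm$depth_test, norm$depth_matched),
                config)
  } else NULL
  if (!is.null(somatic) && nrow(somatic) > 0) {
    germ_key <- if (!is.null(germline) && nrow(germline) > 0)
      paste(germline$gene, germline$state) else character()
    somatic$origin <- ifelse(paste(somatic$gene, somatic$state) %in% germ_key,
                             "germline", "somatic")
  } else if (!is.null(somatic)) {
    somatic$origin <- character()
  }
  list(germline = germline, somatic = somatic)
}

#' Simulate exon coverage for a copy-number trio
#'
#' Poisson read depths per exon for test, matched-normal and
#' reference-normal tracks, with integer copy numbers injected per gene in
#' the chosen compartments (diploid elsewhere).
#'
#' @param panel exon table from [default_panel()].
#' @param mean_depth mean diploid exon depth.
#' @param somatic_cn named integer vector: copies per gene in the test
#'   compartment only.
#' @param germline_cn named integer vector: copies per gene in both test
#'   and matched compartments (inherited events).
#' @param seed RNG seed.
#' @return coverage data frame consumable by
#'   [germline_vs_somatic_split()].
#' @export
simulate_exon_coverage <- function(panel = default_panel(), mean_depth = 200,
                                   somatic_cn = c(), germline_cn = c(),
                                   seed = 1L) {
  stopifnot(mean_depth > 0)
  with_seed(seed, {
    n <- nrow(panel)
    cn_of <- function(cn_map, base = 2) {
      cn <- rep(base, n)
      hit <- panel$gene %in% names(cn_map)
      cn[hit] <- cn_map[panel$gene[hit]]
      cn
    }
    cn_test <- cn_of(somatic_cn)
    g <- cn_of(germline_cn)
    cn_test[panel$gene %in% names(germline_cn)] <-
      g[panel$gene %in% names(germline_cn)]
    cbind(panel,
          depth_test = stats::rpois(n, mean_depth * cn_test / 2),
          depth_matched = stats::rpois(n, mean_depth * g / 2),
          depth_reference = stats::rpois(n, mean_depth))
  })
}
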