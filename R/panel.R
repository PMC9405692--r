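#' Default targeted gene panel (synthetic coordinates)
#'
#' A compact stand-in for a 50-gene glioma panel: the recurrently altered
#' genes seen in the study tables, laid out on synthetic contigs (one
#' coordinate space; no liftover) with a handful of exons per gene. Exon
#' coordinates are 1-based inclusive.
#'
#' @param exons_per_gene exons per gene (default 6).
#' @param exon_bp exon width in bp (default 150).
#' @return data frame: `chrom`, `start`, `end`, `gene`, `exon`.
#' @export
default_panel <- function(exons_per_gene = 6, exon_bp = 150) {
  genes <- c("TP53", "PTEN", "EGFR", "ATRX", "IDH1", "NF1", "SMARCA4",
             "APC", "TSC2", "JAK3", "NSD1", "KMT2D", "LTBP2", "CDKN2A",
             "SPEN", "EPHA6", "PCSK7", "TCF3", "RECQL4", "BRAF", "MTOR",
             "MED12", "PIK3CA", "NOTCH1", "RB1")
  per_contig <- 5L
  rows <- lapply(seq_along(genes), function(i) {
    contig <- paste0("panel", (i - 1L) %/% per_contig + 1L)
    gene_start <- ((i - 1L) %% per_contig) * 100000L + 1L
    exon <- seq_len(exons_per_gene)
    start <- gene_start + (exon - 1L) * 1000L
    data.frame(chrom = contig, start = start, end = start + exon_bp - 1L,
               gene = genes[i], exon = exon, stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}

# every targetable base position of a panel (used to place variant sites)
panel_positions <- function(panel) {
  do.call(rbind, lapply(seq_len(nrow(panel)), function(i)
    data.frame(chrom = panel$chrom[i], pos = panel$start[i]:panel$end[i],
               gene = panel$gene[i], stringsAsFactors = FALSE)))
}
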