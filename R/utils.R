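#' Round half away from zero
#'
#' Rounding as printed tables round (0.025 -> 0.03 at 2 digits), as opposed
#' to the IEC 60559 half-to-even rule used by [base::round()].
#'
#' @param x numeric vector.
#' @param digits number of decimal places.
#' @return rounded numeric vector.
#' @export
round_half_up <- function(x, digits = 0) {
  m <- 10^digits
  sign(x) * floor(abs(x) * m + 0.5) / m
}

#' Allele frequency from read counts
#'
#' @param alt alt-supporting read count.
#' @param depth total read count at the site.
#' @return `alt/depth`; `NA` where `depth` is 0 (undefined, reported missing).
#' @export
allele_frequency <- function(alt, depth) {
  stopifnot(all(alt >= 0, na.rm = TRUE), all(alt <= depth, na.rm = TRUE))
  ifelse(depth > 0, alt / depth, NA_real_)
}

#' Format an allele frequency at a fixed number of decimals
#'
#' Fixed-precision report formatting with half-up rounding, as in printed
#' result tables (0.150, 0.009).
#'
#' @param af numeric allele frequencies.
#' @param digits decimals to keep.
#' @return character vector.
#' @export
format_af <- function(af, digits = 3) {
  out <- formatC(round_half_up(af, digits), format = "f", digits = digits)
  out[is.na(af)] <- NA_character_
  out
}

# Number of decimal places in a printed decimal string ("0.0249" -> 4).
printed_decimals <- function(x) {
  x <- as.character(x)
  has_dot <- grepl(".", x, fixed = TRUE)
  ifelse(has_dot, nchar(sub("^[^.]*\\.", "", x)), 0L)
}

#' Canonical variant identity key
#'
#' Variants are matched across patients and catalogs by rsID when one is
#' known, otherwise by normalized coordinates (the leading "chr" is
#' stripped so hg-style and plain contig labels compare equal).
#'
#' @param chrom,pos,ref,alt coordinate identity (1-based position).
#' @param rsid optional dbSNP identifier; `NA`/empty means unknown.
#' @return character key vector.
#' @export
variant_key <- function(chrom, pos, ref = NA, alt = NA, rsid = NA) {
  n <- max(length(chrom), length(pos), length(ref), length(alt),
           length(rsid))
  rsid <- rep_len(as.character(rsid), n)
  coord <- paste(rep_len(sub("^chr", "", as.character(chrom)), n),
                 rep_len(as.character(pos), n),
                 rep_len(as.character(ref), n), rep_len(as.character(alt), n),
                 sep = ":")
  use_rs <- !is.na(rsid) & nzchar(rsid) & rsid != "-"
  ifelse(use_rs, rsid, coord)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
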