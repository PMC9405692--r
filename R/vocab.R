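#' Diagnosis vocabulary
#'
#' Controlled mapping from free-text diagnostic labels to a diagnosis class.
#' WHO-graded gliomas of any grade (glioblastoma, astrocytoma,
#' oligodendroglioma, oligoastrocytoma, xanthoastrocytoma and spelling
#' variants, diffuse glioma) map to `"glioma"`; primary CNS lymphoma to
#' `"pcnsl"`; metastatic lesions to `"metastasis"`; anything else to
#' `"other"`.
#'
#' @param label character vector of diagnosis labels.
#' @return character vector of classes.
#' @export
#' @examples
#' classify_diagnosis(c("Glioblastoma, Grade 4",
#'                      "Primary Central Nervous System Lymphoma"))
classify_diagnosis <- function(label) {
  label <- tolower(as.character(label))
  out <- rep("other", length(label))
  out[grepl("glioma|glioblastoma|astrocytoma|oligodendroglioma|xanthoastrocytoma|xantoastrocytoma",
            label)] <- "glioma"
  out[grepl("lymphoma", label)] <- "pcnsl"
  out[grepl("metastasis|metastatic", label)] <- "metastasis"
  # a metastatic glioma label would be a contradiction; metastasis wins above
  out
}

#' Normalize a clinical-significance label
#'
#' Collapses ClinVar-style free text onto the controlled vocabulary
#' `pathogenic`, `likely_pathogenic`, `pathogenic/likely_pathogenic`,
#' `uncertain`, `benign`, `none`. Assertion qualifiers such as
#' "FDA recognized" are ignored.
#'
#' @param clinsig character vector.
#' @return character vector on the controlled vocabulary.
#' @export
normalize_clinsig <- function(clinsig) {
  x <- tolower(trimws(as.character(clinsig)))
  x[is.na(x) | x %in% c("", "-", "na", "none", ".")] <- "none"
  out <- rep("none", length(x))
  out[grepl("uncertain", x)] <- "uncertain"
  out[grepl("benign", x)] <- "benign"
  out[grepl("^likely[ _]pathogenic", x)] <- "likely_pathogenic"
  out[grepl("^pathogenic", x)] <- "pathogenic"
  out[grepl("pathogenic/likely[ _]pathogenic", x)] <- "pathogenic/likely_pathogenic"
  out
}

# clinsig values that count as pathogenic-like for tier assignment
PATHOGENIC_CLINSIG <- c("pathogenic", "likely_pathogenic",
                        "pathogenic/likely_pathogenic")

#' Triage tiers, in assignment order
#'
#' @export
TRIAGE_TIERS <- c("CTDNA_CONFIRMED", "COHORT_CURRENT_CONFIRMED",
                  "COHORT_PRIOR_CONFIRMED", "PATHOGENIC_CCFDNA_ONLY",
                  "CARRIER_BENIGN", "DISCARDED")
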