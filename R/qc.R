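#' Fragment-profile QC thresholds
#'
#' The electropherogram categories are exemplars, not numbers, so the
#' cutoffs are explicit configuration: a sample fails as `no_material`
#' when total signal in the cfDNA window is below `min_signal`, and as
#' `genomic_contamination` when the mass fraction above
#' `contaminant_min_bp` exceeds `max_contaminant_fraction` while the cfDNA
#' window signal stays below `min_signal`.
#'
#' @param min_signal minimum abundance in the cfDNA window (unit-agnostic,
#'   same units as the profile).
#' @param max_contaminant_fraction maximum tolerated fraction of total
#'   mass above `contaminant_min_bp`.
#' @param contaminant_min_bp fragments longer than this are genomic
#'   contamination (default 2000 bp).
#' @param window cfDNA size window of interest, bp (default 100-500).
#' @return named list.
#' @export
qc_thresholds <- function(min_signal = 1, max_contaminant_fraction = 0.9,
                          contaminant_min_bp = 2000, window = c(100, 500)) {
  stopifnot(min_signal >= 0, max_contaminant_fraction >= 0,
            max_contaminant_fraction <= 1, window[1] < window[2])
  as.list(environment())
}

# validate a fragment-length profile: data frame length_bp / abundance
check_profile <- function(profile) {
  stopifnot(all(c("length_bp", "abundance") %in% names(profile)),
            all(profile$length_bp > 0), all(profile$abundance >= 0))
  profile
}

#' Abundance in a fragment-size window
#'
#' Sums profile abundance over `[lo_bp, hi_bp]` (inclusive). The default
#' window, 100-500 bp, is the cfDNA size range quantified for yield.
#'
#' @param profile data frame with `length_bp` and `abundance`.
#' @param lo_bp,hi_bp window bounds in bp.
#' @return total abundance in the window; 0 (with a warning) for an empty
#'   histogram.
#' @export
quantify_window <- function(profile, lo_bp = 100, hi_bp = 500) {
  stopifnot(lo_bp < hi_bp)
  if (nrow(profile) == 0 || sum(profile$abundance) == 0) {
    warning("empty fragment profile; window abundance is 0")
    return(0)
  }
  check_profile(profile)
  in_win <- profile$length_bp >= lo_bp & profile$length_bp <= hi_bp
  sum(profile$abundance[in_win])
}

#' Classify a ccfDNA sample from its fragment profile
#'
#' Verdicts mirror the sample-triage categories of capillary
#' electrophoresis QC: `no_material` (fail), `genomic_contamination`
#' (fail: essentially all mass in long genomic fragments and no usable
#' cfDNA signal), `tolerable_contamination` (pass: visible genomic
#' background but a clear cfDNA peak), `clean` (pass).
#'
#' @param profile data frame with `length_bp` and `abundance`.
#' @param thresholds a [qc_thresholds()].
#' @return list with `status` (`"pass"`/`"fail"`), `reason`, and
#'   `cfdna_window_yield`.
#' @export
classify_qc <- function(profile, thresholds = qc_thresholds()) {
  check_profile(profile)
  total <- sum(profile$abundance)
  yield <- if (total == 0) 0 else
    suppressWarnings(quantify_window(profile, thresholds$window[1],
                                     thresholds$window[2]))
  long_frac <- if (total == 0) 0 else
    sum(profile$abundance[profile$length_bp > thresholds$contaminant_min_bp]) / total
  if (total < thresholds$min_signal) {
    verdict <- list(status = "fail", reason = "no_material")
  } else if (long_frac > thresholds$max_contaminant_fraction &&
             yield < thresholds$min_signal) {
    verdict <- list(status = "fail", reason = "genomic_contamination")
  } else if (long_frac > 0) {
    verdict <- list(status = "pass", reason = "tolerable_contamination")
  } else {
    verdict <- list(status = "pass", reason = "clean")
  }
  verdict$cfdna_window_yield <- yield
  verdict
}

#' Right-sided size selection
#'
#' Emulates bead-based removal of fragments longer than the cutoff:
#' abundance above `cutoff_bp` is zeroed, abundance at or below it is
#' untouched (hence idempotent and sub-cutoff mass conserving).
#'
#' @param profile data frame with `length_bp` and `abundance`.
#' @param cutoff_bp retain fragments of at most this length (default 500).
#' @return the filtered profile.
#' @export
right_size_select <- function(profile, cutoff_bp = 500) {
  stopifnot(cutoff_bp > 0)
  check_profile(profile)
  profile$abundance[profile$length_bp > cutoff_bp] <- 0
  profile
}

#' Unpaired two-sample yield comparison
#'
#' Classical Student (equal-variance) two-tailed t-test, matching the
#' study's unpaired yield comparisons; a Welch option is available.
#'
#' @param group_a,group_b numeric yield vectors, each of length >= 2.
#' @param var_equal pool variances (default `TRUE`, Student's test).
#' @return list with `t`, `df`, `p`, `significant` (at 0.05).
#' @export
compare_yields_unpaired <- function(group_a, group_b, var_equal = TRUE) {
  stopifnot(length(group_a) >= 2, length(group_b) >= 2)
  if (stats::var(group_a) == 0 && stats::var(group_b) == 0) {
    if (mean(group_a) == mean(group_b))
      return(list(t = 0, df = length(group_a) + length(group_b) - 2, p = 1,
                  significant = FALSE))
    stop("zero variance in both groups with unequal means: t undefined")
  }
  ht <- stats::t.test(group_a, group_b, var.equal = var_equal)
  list(t = unname(ht$statistic), df = unname(ht$parameter),
       p = ht$p.value, significant = ht$p.value < 0.05)
}

#' Paired pre/post yield comparison
#'
#' Two-tailed paired t-test on the per-patient differences. The degenerate
#' case (all differences identical, zero variance) is reported as p = 1
#' with a warning rather than an error.
#'
#' @param pre,post numeric vectors of equal length >= 2, matched by
#'   position.
#' @return list with `t`, `df`, `p`, `significant`, `degenerate`.
#' @export
compare_yields_paired <- function(pre, post) {
  if (length(pre) != length(post)) stop("pre/post length mismatch")
  stopifnot(length(pre) >= 2)
  d <- post - pre
  if (stats::var(d) == 0) {
    warning("zero variance of paired differences; reporting p = 1")
    return(list(t = NA_real_, df = length(d) - 1, p = 1,
                significant = FALSE, degenerate = TRUE))
  }
  ht <- stats::t.test(post, pre, paired = TRUE)
  list(t = unname(ht$statistic), df = unname(ht$parameter), p = ht$p.value,
       significant = ht$p.value < 0.05, degenerate = FALSE)
}
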