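---
title: "Triage of plasma variants in matched tumor/germline/plasma panels: methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Triage of plasma variants in matched tumor/germline/plasma panels: methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(plasmatriage)
```

## The problem

Circulating cell-free DNA (ccfDNA) in plasma is a mixture: mostly DNA shed
by normal cells, plus - in cancer patients - a small circulating tumor DNA
(ctDNA) component. In brain tumors that component is particularly scarce,
so a targeted-panel liquid-biopsy analysis has to (i) verify that a plasma
sample contains usable cfDNA at all, (ii) call somatic variants from the
matched tumor against whole-blood germline DNA, (iii) ask which of those
somatic variants reappear in plasma, and (iv) triage plasma variants that
are *absent* from germline DNA but never seen in the sampled tumor
fragment - candidates for tumor heterogeneity the biopsy missed. This
package implements those four stages, a simplified exon depth-ratio
copy-number caller, and a synthetic cohort generator so that every stage
is testable without controlled-access patient data.

## Compartment model and somatic classification

Every stage consumes per-site read counts: depth $N$ and alt-supporting
reads $k$, giving the variant allele frequency $\mathrm{AF} = k/N$, in
three compartments per patient (tumor tDNA, germline gDNA, plasma
ccfDNA).

A candidate site is classified from the tumor/germline 2x2 table
(alt/ref x tumor/germline) by the two-sided conditional Fisher exact
test. The two-sided p-value is the sum over the hypergeometric support of
all table probabilities not exceeding the observed one (relative tie
tolerance $1+10^{-7}$, the convention of standard implementations). A
site is **somatic** when

* $p \le 0.05$ (configurable; the conventional cutoff of somatic
  extraction tools),
* germline AF $< 1\%$ (strict: AF exactly 0.01 fails), and
* tumor AF $\ge 1\%$.

A germline-heterozygous site (gDNA AF in $[0.25, 0.75]$, a band we had to
choose since none is standard) whose tumor AF leaves the band with a
significant p-value is **LOH**; both compartments heterozygous-or-higher
is **germline**; anything else is **unknown**.

Retention then applies the literal thresholds: tumor coverage $\ge 10$
reads, tumor alt reads $\ge 3$, tumor AF $\ge 1\%$, germline AF $< 1\%$,
and no strand-supporting-read bias. The strand rule is our
concretization of an informally stated filter: Fisher exact test on the
strand x allele table at $p < 0.05$ *and* at least 90% of alt reads on
one strand; both knobs are configurable, and sites without strand
information are never flagged. Finally, calls matching a common-variant
catalog entry at population AF $> 0.001$ are removed (so rare catalogued
pathogenic variants survive), as are calls whose SIFT score predicts a
tolerated change. SIFT direction deserves a note: the source material
for this pipeline prints "damaging (>0.05)", which inverts the universal
SIFT convention; we default to the standard damaging $< 0.05$ and expose
`sift_damaging_is_high` for the literal reading.

One stated rule is self-contradictory in its source ("supported by at
least 10 raw reads and found only in tumor samples were filtered out and
treated as potentially pathogenic"); we resolve it as *retain* -
tumor-only variants at adequate coverage stay in the somatic set.

## Plasma concordance and UMI consensus

Plasma libraries carry unique molecular identifiers (UMIs): every
original molecule is tagged before PCR, so duplicate reads collapse to
one consensus observation and most sequencing errors vote themselves
out. `collapse_umi()` takes the family-majority allele per UMI (ties are
ambiguous and excluded - base qualities are out of scope), giving
consensus depth = number of unambiguous families.

With $d$ duplicates per family and per-read error $e$, the residual
consensus error is the majority-vote tail, $\approx 3e^2$ for $d = 3$ -
three orders of magnitude below the raw read error at $e = 10^{-3}$.
This is why detection thresholds as low as 3 alt consensus reads are
usable at consensus depths of 1000-2000: on *raw* counts,
$P(\mathrm{Bin}(1000, 10^{-3}) \ge 3) \approx 0.08$ would flood the
analysis with false positives, while on consensus counts the same
threshold has a false-detection probability near $10^{-8}$. The
detection properties in the test suite therefore run on consensus
counts, which is the pipeline's operating point.

The concordance rule itself (`detect_ctdna()`): a variant already
classified somatic in the matched tumor is detected in plasma when its
consensus alt count is $\ge 3$ (configurable). There is deliberately no
plasma AF floor: concordant variants at AF 0.009 are real at these
depths, and the 1% AF rule applies to the tumor side only.

## Plasma-only triage

`select_ccfdna_only()` keeps variants with plasma support but germline
absence. Two absence rules exist because the use cases differ:

* strict (pathogenic plasma-only tier): gDNA alt = 0;
* relaxed (cohort-confirmation tiers): gDNA alt $\le 3$ *and*
  gDNA AF $< 0.1$ - the confirmation evidence tolerates a stray
  germline read or three (observed up to 2 of 39 reads, AF 0.051, in
  variants worth confirming), and the AF guard only excludes genuinely
  germline-looking sites.

The triage evidence floor is 2 plasma consensus reads (the observed
minimum among reportable plasma-only variants), one read below the
concordance threshold; both are separate configuration knobs.

`classify_tier()` assigns exactly one tier by the first matching rule,
in fixed order: same-patient tumor confirmation, current-cohort
confirmation, prior-cohort confirmation, pathogenic plasma-only
(pathogenic-like ClinVar significance, or COSMIC-registered and
population AF $\le 0.001$; absence from population databases counts as
rare), benign carrier, discarded. Uncertain-significance variants can
qualify only through the COSMIC+rarity arm - matching how such variants
are actually reported. The rule trail is recorded per call, so every
tier decision is auditable, and the tier partition is total by
construction.

## Fragment-length QC

ccfDNA fragments are nucleosome-sized: 120-220 bp with the peak at
167 bp, plus dimer/trimer multiples; genomic contamination shows up as
fragments beyond 2000 bp. The QC verdicts mirror electropherogram
triage: `no_material` (window signal below a configurable floor),
`genomic_contamination` (contaminant mass fraction above 0.9 *and* no
usable cfDNA signal), else pass as `clean` or
`tolerable_contamination`. The thresholds are explicit configuration
because the underlying categories are exemplars, not numbers.
`right_size_select()` zeroes abundance above 500 bp (idempotent,
sub-cutoff mass conserving), and `quantify_window()` integrates the
100-500 bp yield. Yield comparisons use the classical Student
(equal-variance) two-tailed t-test - matching the study design they
emulate - with a Welch flag, and the paired test reports the degenerate
zero-variance case as p = 1 with a warning rather than failing.

## Copy-number ratio caller

The CNA stage is an intentionally simple, documented caller: per-exon
depths are normalized to panel-mean 1 per compartment, the per-exon
$\log_2$ ratio is thresholded (gain at $\ge \log_2 1.25 \approx 0.32$,
i.e. 2.5 copies; loss at $\le -0.42$, i.e. 1.5 copies), and adjacent
same-state exons within a gene are merged (run-length encoding; merging
never changes an exon's state). Germline events are called blood vs a
reference normal track; somatic events test-compartment vs matched
blood; a somatic call sharing gene and state with a germline call is
reported as germline-origin. We deliberately do not implement HMM
segmentation, GC correction, purity correction or B-allele support;
single-exon borderline calls are noise-prone and real analyses should
require multi-exon support.

## The synthetic cohort generator

The generator *defines* the study conditions for all property tests:

* 84 patients; diagnosis mix dominated by grade-4 glioma with a grade-3
  minority, 2 PCNSL and 2 metastatic patients (the cohort structure the
  analysis is designed for);
* 20 germline heterozygous sites per patient at allele fraction 0.5 in
  all compartments;
* 5 clonal somatic sites per patient with tumor AF uniform in
  $[0.2, 0.7]$ (clonal-range VAFs);
* patient ctDNA fraction uniform in $[0, 0.1]$ - most patients carry
  little or no detectable ctDNA, as in real plasma from brain-tumor
  patients;
* per-read error $10^{-3}$ (post-trimming substitution rate of modern
  short-read data);
* fixed per-compartment depths 200/200/2000 (gDNA/tDNA/ccfDNA), typical
  of a broad tumor panel and a deep narrow plasma panel. Depths are
  deterministic: coverage variation is not part of the model, and the
  choice of 200x germline coverage matters - the strict germline AF
  $< 1\%$ gate needs enough reads that a single stray error read does
  not cross 1%;
* plasma alt counts Binomial with the linear mixture rate
  $f \cdot a + (1 - f) \cdot e$ (read-level view), and a molecule-level
  UMI view (`simulate_umi_reads()`) where alt molecules are
  $\mathrm{Bin}(n_\mathrm{families}, f \cdot a)$ and errors enter per
  duplicate read;
* fragment lengths as a categorical mixture over the 167/334/501 bp
  nucleosomal peaks (weights 0.80/0.15/0.05 - multimers are reported to
  exist without stated proportions) plus an optional >2000 bp
  contaminant peak.

Seeds are explicit everywhere (patient $i$ uses `seed + i`; no global
RNG state leaks), so identical spec + seed reproduces byte-identical
outputs, which the suite asserts through a VCF round trip.

What the generator does **not** emulate - and what passing tests
therefore do not show about real data: mapping and alignment artifacts,
GC and capture bias, overdispersed coverage, subclonal tumor structure,
CHIP (clonal hematopoiesis) variants in the germline compartment, and
fragment-length differences between tumor- and normal-derived plasma
molecules.

## Numerical and design choices

* Fisher p-values are computed by direct summation over the
  hypergeometric support (exact; verified against a brute-force
  binomial-coefficient enumeration to $10^{-12}$ on all tables with
  margins $\le 30$).
* Boundary semantics are literal everywhere: "at least" is $\ge$,
  "less than" is $<$; the suite pins coverage 9/10, 3-alt, and
  1%-germline boundaries.
* Report AFs are formatted with half-up rounding at the table's printed
  precision (0.025 prints as 0.03, not the half-to-even 0.02).
* Problem sizes in the test suite (replicate counts of 100-600 per
  property, cohorts of a few patients for structural tests) were chosen
  so each property's Monte-Carlo error is far below its asserted
  margin - e.g. somatic sensitivity is asserted at $\ge 0.95$ where the
  analytic expectation under the study conditions is
  $\approx 0.98$, with 1000 simulated somatic sites behind the
  estimate.
* The headline patient counts (8 ctDNA-positive, 5 glioma, 25
  pathogenic plasma-only, 16 cohort-confirmed) are recomputed from the
  packaged table transcriptions by `run_fixture_report()`; a published
  "32 of 84" aggregate is *not* targeted, because no single inclusion
  rule we can state reproduces it from the printed tables - the 25 and
  16 counts are internally consistent and are what the package
  reproduces.

## Worked example

```{r example}
rep <- run_fixture_report()
rep

cfg <- run_config(seed = 7, cohort = cohort_spec(n_patients = 5))
run_pipeline(cfg)
```

## Limitations

The package starts from per-site counts: read trimming, alignment,
duplicate marking and variant-calling engines are out of scope, as are
liftover between genome builds (the synthetic cohort lives in one
coordinate space), live annotation-database queries, and
tumor-fraction estimation from plasma AFs. The fixture catalogs contain
exactly the variants needed to reproduce the packaged tables plus the
synthetic panel; they are not a general annotation resource.
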