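Package: plasmatriage
Title: Variant Triage for Circulating Tumor DNA in Matched Tumor/Germline/Plasma Panels
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"), email = "author@example.org")
Description: Analysis pipeline for detecting circulating tumor DNA (ctDNA) and
    potentially pathogenic plasma-only variants in targeted-panel sequencing of
    brain-tumor patients. Starting from per-site read counts in three matched
    compartments (tumor DNA, whole-blood germline DNA, plasma cell-free DNA),
    the package calls somatic variants with a Fisher-exact tumor/germline
    classifier and literal retention thresholds, collapses plasma UMI read
    families to consensus counts, tests tumor variants for presence in plasma,
    triages plasma-only variants into pathogenicity/confirmation tiers against
    annotation and cohort catalogs, performs fragment-length quality control of
    cell-free DNA, and calls copy-number gains from exon-level depth ratios.
    A synthetic cohort generator reproduces the statistical structure the
    analysis assumes (germline heterozygous sites, clonal tumor variants,
    plasma mixtures at a ctDNA fraction, UMI families, nucleosomal fragment
    sizes) so every stage is testable without controlled-access data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    vcfR
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    knitr,
    rmarkdown
Config/testthat/edition: 3
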