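Package: fieldscape
Title: Occult Tumor and Field-Effect Detection in Cancer-Adjacent Tissue
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Multi-platform analysis of histologically normal, cancer-adjacent
    breast tissue. Detects occult tumor cells and field-cancerization effects
    from DNA methylation beta values by per-sample regression on matched tumor
    profiles; calls copy-number evidence of tumor via 50% reciprocal-overlap
    segment matching with blood exclusion; classifies somatic mutation burden
    from variant-allele-fraction pileups behind a Fisher-exact somatic filter;
    clusters extratumoral expression by NMF consensus clustering with
    consensus-matrix silhouettes and permutation (SAM-style Wilcoxon)
    differential abundance; and integrates per-platform defect calls with
    Kaplan-Meier and Cox proportional-hazards survival models. Ships a
    seeded synthetic-data generator for tumor/blood/adjacent triplets so
    every stage is testable by parameter recovery.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    graphics,
    survival
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
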