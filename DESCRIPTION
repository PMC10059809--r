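Package: bcaamr
Title: Two-Sample Mendelian Randomization of Branched-Chain Amino Acids
    and Cardiovascular Disease
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Complete two-sample Mendelian randomization (MR) workflow for
    assessing the causal effect of genetically predicted serum branched-chain
    amino acid (BCAA) concentrations on coronary artery disease and related
    cardiovascular outcomes from GWAS summary statistics. Provides instrument
    construction (genome-wide significance filtering, cross-trait
    deduplication, linkage-disequilibrium pruning, confounder-gene exclusion),
    allele harmonization with palindromic-variant policies, six causal
    estimators (random- and fixed-effects inverse-variance weighted, MR-Egger,
    simple and weighted median, robust adjusted profile score, MR-PRESSO
    outlier simulation), heterogeneity and leave-one-out diagnostics, two-step
    MR mediation with delta-method uncertainty, DerSimonian-Laird
    random-effects meta-analysis, multiplicity control (Benjamini-Hochberg and
    Bonferroni) with Ward clustering of cross-trait Z-scores, and seeded
    synthetic summary-statistics generators for property-based validation. The
    17-variant BCAA instrument and its outcome associations are bundled as a
    plain-text fixture so the headline estimates are reproducible offline.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    graphics,
    metafor,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
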