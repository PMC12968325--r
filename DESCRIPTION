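Package: misscalib
Title: Gene-Specific Calibration of Missense Pathogenicity Predictors for ACMG/AMP PP3/BP4 Evidence
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"), email = "author@example.org")
Description: Calibrates in silico missense pathogenicity prediction tools
    (CADD, REVEL, BayesDel, AlphaMissense) for a single gene and disease by
    fitting a population-prior-weighted logistic regression of pathogenicity on
    prediction score within a multiple-imputation framework over variants of
    uncertain significance, pooling by Rubin's rules, and locating score
    thresholds where the 95% lower bound of the positive likelihood ratio
    reaches the likelihood-ratio targets of the ACMG/AMP evidence strength
    levels (PP3/BP4 supporting through very strong). Includes the maximum
    tolerated population allele frequency benign rule, repeated stratified
    hold-out AUC evaluation, critical-domain enrichment statistics, point-based
    ACMG/AMP evidence combination with the PM1+PP3 cap, a curated variant-table
    layer with protein HGVS parsing, and a synthetic-data generator with exact
    distributional oracles for end-to-end validation. Reference calibration
    targets the PHOX2B homeodomain gene associated with congenital central
    hypoventilation syndrome.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr,
    Biostrings,
    vcfR,
    pROC,
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
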