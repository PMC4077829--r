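Package: mosaicsnv
Title: Multi-Tissue Exome SNV Mosaicism Analysis
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Tools for comparing single-nucleotide variant (SNV) callsets
    across many tissues of one individual to characterise somatic mosaicism.
    Provides GATK-style hard filtering of per-tissue VCF callsets, pairwise
    and N-way set algebra over variant keys (tissue-specific SNVs, the
    common-to-all core, germ-layer sharing summaries), per-chromosome
    distribution statistics with feature correlations, read-depth and
    variant-allele-fraction based developmental-timing heuristics, a
    synthetic developmental-mosaicism simulator with lineage-structured
    truth sets, and a generic hypergeometric over-representation test for
    annotated gene lists.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    dplyr,
    tibble,
    readr,
    rlang,
    vcfR,
    jsonlite,
    stats,
    utils
Suggests: testthat (>= 3.0.0), optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
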