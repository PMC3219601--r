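Package: cistrometry
Title: Integrative Cistrome Analysis for Pioneer-Factor Studies
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for the integrative analysis that links transcription-factor
    cistromes to an estrogen-driven transcriptional program: BED interval
    algebra under the one-base-pair overlap rule, TRANSFAC position weight
    matrix screening of peak sequences, genome-structure-corrected (block
    resampling) overlap significance, three-way Venn partitioning of
    cistromes, TSS-window enrichment ratios relating binding-site classes to
    responsive genes, microarray-style differential expression with
    median-reference normalization, chromatin-accessibility signal
    aggregation by site class, and expression-stratified metastasis-free
    outcome analysis. A synthetic-data module generates every input with
    planted ground truth so the whole pipeline is testable end to end.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    IRanges,
    Biostrings,
    survival,
    stats,
    utils,
    graphics
Suggests:
    testthat (>= 3.0.0),
    withr,
    jsonlite
Config/testthat/edition: 3
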