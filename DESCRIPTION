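Package: spliceflank
Title: Alternative-Splicing Event Quantification and Splice-Flanking Motif Enrichment
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for the downstream analysis of splicing-factor perturbation
    experiments in plants: construction of alternative-splicing event catalogues
    (alternative 5'/3' splice site, retained intron, skipped exon) from transcript
    annotation, percent-spliced-in (psi) and delta-psi statistics from isoform
    abundance (TPM) tables with replicate-level significance testing, extraction of
    the twenty labeled splice-flanking sequence windows around each event class,
    degenerate-motif density and chi-squared enrichment statistics stratified by
    the sign of delta-psi, consensus gene-set logic for multi-pipeline differential
    expression and RNA-immunoprecipitation enrichment, hypergeometric term
    enrichment, W-box promoter scans, and a fully seeded synthetic-data generator
    (genome, annotation, quantifications, support tables) with known ground truth.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    Biostrings,
    rtracklayer,
    jsonlite,
    stats,
    utils,
    tools,
    graphics
Suggests: testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
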