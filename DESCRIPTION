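Package: evoreseq
Title: Parallel Evolution Analysis for Evolve-and-Resequence Experiments
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for identifying parallel adaptive mutations from
    whole-population (pooled) sequencing of experimentally evolved bacterial
    populations. Implements the variant-identification cascade used in
    evolve-and-resequence studies (allele-frequency floor, effect-class
    selection, mutation-accumulation control blacklisting, and a Levene's-test
    filter for systematic artifact sites), gene- and subsystem-level
    parallelism statistics, mutator flagging, cumulative gene frequencies and
    unique-allele spectra, and a peptide-to-protein abundance roll-up with
    per-protein differential testing for population proteomics. A synthetic
    evolve-and-resequence generator with truth labels makes every stage of the
    pipeline verifiable without external sequencing data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    GenomicRanges,
    IRanges,
    S4Vectors,
    rtracklayer,
    Biostrings
Suggests:
    testthat (>= 3.0.0),
    car,
    vcfR,
    withr,
    jsonlite,
    knitr,
    rmarkdown
Config/testthat/edition: 3
VignetteBuilder: knitr
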