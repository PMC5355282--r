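Package: editome
Title: Calling and Characterising the RNA Editome from Matched DNA/RNA Pileups
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: A tidyverse-native toolkit for A-to-I RNA editing analysis in
    matched tumor/normal cohorts. Calls RNA editing sites from per-position
    DNA and RNA pileup tables with a quality-aware filter cascade (binomial
    sequencing-error test, strand and read-position bias, repeat/homopolymer/
    splice-region exclusion, genomic-DNA homozygosity), detects hyper- and
    hypo-editing between paired tumor and normal samples, and quantifies
    downstream consequences: editing rates and spectra, region and Alu
    distributions, amino-acid consequences, percent-spliced-in coupling with
    a coverage-weighted editing index, RPKM expression, and editing-level to
    expression correlation. Includes a synthetic-data generator that emulates
    trios of matched normal/primary/metastatic samples with ground-truth
    tables for recovery benchmarking.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    dplyr (>= 1.1.0),
    tidyr,
    purrr,
    tibble,
    readr,
    stringr,
    rlang,
    ggplot2,
    generics,
    withr,
    stats,
    utils,
    Biostrings,
    GenomicRanges,
    rtracklayer,
    vcfR
Suggests:
    testthat (>= 3.0.0),
    jsonlite
Config/testthat/edition: 3
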