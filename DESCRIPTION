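Package: sirtron
Title: Detection and Analysis of Small Interfering RNA Clusters in Plant Genomes
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A tidyverse-native pipeline for detecting siRNA-enriched genomic
    clusters from aligned small-RNA sequencing data and characterising their
    regulatory and evolutionary properties. Reads are filtered (18-30 nt, no
    mismatches, up to five mapping sites, non-coding RNA removal) and
    normalised to reads per million; clusters are detected by one-dimensional
    density clustering (DBSCAN) with the neighbourhood radius selected from
    the k-distance curve; clusters are associated with host genes and their
    expression dynamics correlated with gene expression; feature-wise
    enrichment odds ratios and chromosomal positioning profiles are computed;
    and evolutionary conservation of cluster regions is tested with a 25-nt
    binned, size-matched resampled t-test. A synthetic-data module generates
    fully ground-truthed inputs (annotation, read libraries, expression
    tables, conservation tracks) so that every stage is testable end to end.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    dplyr,
    tidyr,
    purrr,
    tibble,
    rlang,
    readr,
    stringr,
    ggplot2,
    stats,
    methods,
    utils,
    tools,
    jsonlite,
    yaml,
    S4Vectors,
    IRanges,
    GenomicRanges,
    Biostrings,
    generics
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse,
    knitr,
    rmarkdown
Config/testthat/edition: 3
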