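Package: medapop
Title: Population Genomics of Wild Medaka Founder Panels
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for characterizing a wild medaka (Oryzias latipes) founder
    population and inbred strains from resequencing data: reference-assembly
    patching from deep-coverage consensus calls, windowed heterozygosity and
    inbreeding coefficients, codon-enumeration tests for depletion of
    protein-altering variants, linkage-disequilibrium decay and Gabriel
    haplotype blocks, EHH/iHS selection scans with a composite windowed
    filter, ABBA-BABA introgression tests with a ghost-population control,
    distance-based phylogenetics and in-silico mitotyping, post-processing of
    pairwise sequentially Markovian coalescent output, and broad-sense
    heritability of morphometric traits.  A built-in sequentially Markov
    coalescent simulator generates phased haplotypes, trios, inbred lines,
    sweeps and admixed quartets so every stage is testable on synthetic data.
License: MIT
Encoding: UTF-8
Depends:
    R (>= 4.1)
Imports:
    tibble,
    dplyr,
    purrr,
    rlang,
    readr,
    ggplot2,
    generics,
    stats,
    utils,
    tools,
    ape,
    phangorn,
    cluster,
    vcfR,
    Biostrings
Suggests:
    testthat (>= 3.0.0),
    rtracklayer,
    GenomicRanges,
    jsonlite,
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
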