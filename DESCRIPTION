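Package: milkscan
Title: Selection-Signature Scans and Expression Validation for Divergent Milk-Yield Sheep
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A reusable pipeline for detecting selective sweeps between
    high- and low-milk-yield sheep populations from diploid SNP genotypes:
    variant quality control (call rate, minor-allele frequency, missingness,
    Hardy-Weinberg exact test, linkage-disequilibrium pruning), population
    structure (genomic relationship matrix, principal components,
    identity-by-state distances, neighbour-joining trees), three windowed
    selection statistics (Weir-Cockerham F_ST, nucleotide-diversity ratio,
    Z-transformed pooled heterozygosity) intersected at a top-percentile
    cutoff, candidate-gene annotation with hypergeometric term enrichment,
    and a validation stage linking qPCR delta-CT relative expression to milk
    yield and to breeding values estimated by an animal-model BLUP solved
    through Henderson's mixed-model equations. A synthetic-data module
    generates genotypes with planted sweeps, pedigrees with known breeding
    values, and qPCR tables with a known expression-yield slope, so every
    stage is testable against ground truth.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    dplyr,
    tibble,
    tidyr,
    purrr,
    rlang,
    readr,
    stringr,
    ggplot2,
    vcfR,
    ape,
    Matrix,
    GenomicRanges,
    IRanges,
    rtracklayer,
    S4Vectors,
    BiocGenerics,
    generics,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr,
    knitr,
    rmarkdown,
    jsonlite
Config/testthat/edition: 3
VignetteBuilder: knitr
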