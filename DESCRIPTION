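Package: landgea
Title: Landscape Genomics Pipeline for Genotype-Environment Association
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: An end-to-end landscape-genomics inference chain for diploid SNP
    panels of geo-referenced plant accessions: genotype quality control and
    PLINK-style linkage-disequilibrium pruning, genotype principal component
    analysis and cluster inference, Weir-Cockerham Fst and two-level AMOVA,
    forward selection of non-collinear climate variables, partial redundancy
    analysis with four-model variance partitioning and Mahalanobis-distance
    outlier detection, latent factor mixed model and PC-corrected per-SNP
    genotype-environment association scans with genomic-inflation calibration
    and Storey q-values, sliding-window diversity statistics (nucleotide
    diversity, Watterson's theta, Tajima's D), LD-decay estimation with
    Hill-Weir curve fitting, and candidate-interval/gene mapping. Includes a
    synthetic landscape-data generator with known adaptive loci so every stage
    is testable without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.2)
Imports:
    methods,
    stats,
    utils,
    tools,
    MASS,
    S4Vectors,
    IRanges,
    GenomicRanges,
    vcfR,
    rtracklayer,
    minpack.lm,
    yaml
Suggests:
    testthat (>= 3.0.0),
    vegan,
    withr,
    jsonlite,
    optparse,
    knitr,
    rmarkdown
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
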