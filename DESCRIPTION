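Package: medipnet
Title: CpG-Density-Corrected MeDIP-seq Methylome Analysis and
    Co-Methylation Networks
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Analysis toolkit for MeDIP-seq (methylated DNA
    immunoprecipitation sequencing) methylomes. Computes CpG
    coupling factors on an overlapping genome bin grid, fits a
    calibration curve of signal intensity against local CpG density,
    and derives relative methylation scores corrected for CpG-density
    bias. Annotates CpG islands by genomic location, builds CGI
    shores, and classifies promoters by CpG content (HCP/ICP/LCP).
    Ranks tissue-specific differentially methylated regions by the
    coefficient of variance SD/(mean+1), tests feature-class
    enrichment by observed/expected ratios with a chi-square
    goodness-of-fit, and characterizes sample structure through
    correlation, hierarchical clustering, PCA, between-individual
    difference analysis and genic metaprofiles. Builds signed
    weighted co-methylation networks with topological overlap,
    detects modules, and relates module eigengenes to tissue traits.
    Ships a synthetic methylome generator with planted
    tissue/individual effects so every stage is testable end to end.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.2)
Imports:
    BiocGenerics,
    GenomicRanges,
    IRanges,
    S4Vectors,
    GenomeInfoDb,
    SummarizedExperiment,
    rtracklayer,
    stats,
    utils,
    tools,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr,
    jsonlite
Config/testthat/edition: 3
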