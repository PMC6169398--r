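Package: clinalscan
Title: Landscape Genomics of Clinal Adaptation from SNP Panels
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Tools for dissecting clinal adaptation in georeferenced crop
    germplasm panels from genome-wide SNP genotypes. Implements genotype
    import and quality filtering, windowed population-genetic statistics
    (nucleotide diversity, Tajima's D, Weir-Cockerham FST, linkage
    disequilibrium decay), population structure analysis (PCA, DAPC,
    neighbor-joining), redundancy-analysis variance partitioning of SNP
    variation into climate, space, and climate-collinear-with-space
    fractions with a permutation significance test, common-garden BLUPs,
    mixed-model and multi-locus mixed-model genome-wide association scans,
    naive environmental association scans with empirical outlier selection,
    and candidate-gene colocalization and enrichment tests. A synthetic
    landscape generator with known truth supports calibration and power
    analysis of the whole pipeline.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    MASS,
    ape,
    lme4,
    vcfR,
    rtracklayer,
    GenomicRanges,
    S4Vectors,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    vegan
Config/testthat/edition: 3
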