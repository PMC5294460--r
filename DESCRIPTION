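Package: genegwas
Title: Two-Stage Gene-Based Genome-Wide Association Testing
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Gene-based genome-wide association analysis for quantitative
    traits: genotype quality control, VanRaden genomic relationships,
    population-structure principal components, fixed-effect phenotype
    adjustment, window-based SNP-to-gene assignment, a two-stage gene test
    (within-gene PCA orthogonalization followed by Fisher's combination of
    per-component p-values against a chi-square reference with 2K degrees
    of freedom), a single-marker mixed-linear-model scan with
    eigendecomposition REML, and Manhattan/Q-Q reporting. Includes a
    synthetic diploid population simulator with block linkage
    disequilibrium, polygenic and gene-localized causal architecture, and
    writers/readers for PLINK text, VCF, BED, GFF3 and TSV tables.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    GenomicRanges,
    IRanges,
    S4Vectors,
    rtracklayer,
    vcfR
Suggests:
    testthat (>= 3.0.0),
    jsonlite
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
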