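Package: apohm
Title: Detection of Driver APOBEC Hotspot Mutations in Cancer Whole Genomes
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Tools to characterise APOBEC mutagenesis in tumor whole-genome
    sequencing cohorts and to separate driver from passenger hotspot
    mutations. Implements per-sample TCW fold-enrichment scoring and
    APOBEC3A/3B tetranucleotide attribution, variant copy number and cancer
    cell fraction estimation, 1-Mbp genomic tracks of mutational load and
    ChIP-seq-derived DNA accessibility, detection and nearest-neighbor
    thermodynamic scoring of DNA hairpin-loop structures at mutated sites,
    twin-mutation (didymi) classification, and a covariate-adjusted Poisson
    background model with exact Poisson tests and per-group
    Benjamini-Hochberg correction for calling driver hotspot mutations.
    A simulation module generates synthetic hotspot catalogs and cohorts
    for statistical power analysis and package fixtures.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    Biostrings,
    Rsamtools,
    GenomicRanges,
    GenomeInfoDb,
    IRanges,
    S4Vectors,
    vcfR
Suggests:
    testthat (>= 3.0.0),
    knitr,
    jsonlite,
    optparse
Config/testthat/edition: 3
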