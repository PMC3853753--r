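Package: tillingr
Title: Analysis Toolkit for EMS TILLinG Mutant Populations
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Quantitative machinery for TILLinG (Targeting Induced Local
    Lesions in Genomes) screens of EMS-mutagenized plant populations:
    codon-level classification of induced point mutations against gene
    models (silent, missense, truncation, intronic), mutation-density
    estimation from pooled amplicon screens with exact Poisson confidence
    intervals, genome-wide mutation-load extrapolation, sequence-context
    bias statistics around mutated G bases, k-fold one-dimensional pooling
    design and deconvolution across 96-well plates, population phenotype
    tabulation with genotype-phenotype concordance, and a seeded synthetic
    EMS-population generator so every stage can be exercised and validated
    without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    methods,
    stats,
    utils,
    tools,
    Biostrings,
    IRanges,
    GenomicRanges,
    rtracklayer,
    jsonlite
Suggests: testthat (>= 3.0.0), withr
Config/testthat/edition: 3
biocViews: Genetics, SNP, Sequencing
RoxygenNote: 7.3.3
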