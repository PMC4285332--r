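Package: its2otu
Title: OTU-Based Genotyping of Multicopy ITS2 rDNA Amplicons
Version: 0.1.0
Authors@R:
    person("Package", "Author", , "author@example.org", role = c("aut", "cre"))
Description: An operational-taxonomic-unit (OTU) pipeline for genotyping
    Symbiodinium (Symbiodiniaceae) diversity from multicopy ITS2 rDNA
    amplicon reads. Covers demultiplexing, primer trimming, sequence-based
    quality filtering, dereplication, singleton removal, a simplified
    abundance-skew chimera flagger, pairwise global alignment with
    gap-run-compressed uncorrected distances, two-tier average-neighbour
    clustering (clade binning then within-clade species/type OTUs),
    representative picking and nearest-reference annotation. Includes
    taxonomic cut-off calibration from isoclonal-culture controls,
    rank-abundance/rarefaction diversity summaries, and a seeded synthetic
    read generator emulating intragenomic rDNA variation, rDNA copy-number
    bias, homopolymer errors and chimeras so every stage is testable
    without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Biostrings,
    mclust,
    methods,
    Rcpp,
    stats,
    utils,
    withr
LinkingTo:
    Rcpp
Suggests:
    jsonlite,
    knitr,
    optparse,
    rmarkdown,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
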