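Package: viroshare
Title: Household Virome Sharing, Persistence and Transmission Analysis
Version: 0.99.0
Authors@R: person("Package", "Author", email = "maintainer@example.org",
    role = c("aut", "cre"))
Description: Tools for analysing longitudinal household virome cohorts from
    assembled contigs. Implements all-against-all nucleotide homology search
    (seed-and-extend local alignment with Karlin-Altschul significance),
    per-virome shared-homologue fractions, Sorensen similarity and
    Bray-Curtis distances with principal coordinates analysis, a resampling
    test for individual- and household-specific virome overlap, single-linkage
    clustering of contigs into global viruses for persistence tracking, and a
    presence/absence rule for calling putative virus transmissions between
    housemates with treatment-arm directionality. Includes a household-cohort
    simulator with planted ground truth for validating the full pipeline.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    methods,
    stats,
    utils,
    tools,
    Rcpp,
    Biostrings,
    S4Vectors,
    igraph,
    jsonlite,
    yaml
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
biocViews: Metagenomics, Sequencing, Clustering, Microbiome
RoxygenNote: 7.3.3
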