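Package: asrfam
Title: Genome-Wide Characterization of Plant ASR Gene Families
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.com",
           role = c("aut", "cre"))
Description: Toolkit for genome-wide surveys of the abscisic acid-, stress-
    and ripening-induced (ASR) gene family in allopolyploid wheat and related
    grasses. Covers profile-based family identification from a proteome,
    protein physicochemistry (molecular weight, isoelectric point, GRAVY),
    progressive multiple alignment and neighbor-joining phylogenies with
    bootstrap supports, tandem/segmental duplication classification and
    homoeolog-group assignment across the A/B/D subgenomes, ZOOPS
    expectation-maximization motif discovery, position-weight-matrix promoter
    scanning with exact p-values, RNA-seq expression heatmap preparation and
    2^-ddCt qPCR quantification, plus a seeded synthetic-genome generator so
    the whole pipeline is testable without external downloads.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Biostrings,
    Rcpp,
    ape,
    igraph,
    jsonlite,
    methods,
    stats,
    utils,
    yaml
LinkingTo: Rcpp
Suggests:
    phangorn,
    rtracklayer,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
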