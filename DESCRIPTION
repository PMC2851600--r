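Package: synmapr
Title: Synteny Mapping Between a Diploid Genetic Map and a Duplicated Genome
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.com",
    role = c("aut", "cre"))
Description: Infers one-to-two ortholog assignments, syntenic blocks,
    physical-to-genetic distance ratios, electronically mapped loci, extended
    syntenic blocks and within-genome duplication blocks from filtered
    sequence-similarity hits (BLAST tabular) and a genetic map, following the
    comparative-mapping design used for a diploid legume genetic map against a
    paleopolyploid relative's genome sequence. Ships a whole-genome-duplication
    simulator (fractionation, segmental rearrangement, inversion, recombination
    suppression near pericentromeres) with a full ground-truth event log so
    every pipeline stage can be validated without external data.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    IRanges,
    stats,
    utils
Suggests:
    jsonlite,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
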