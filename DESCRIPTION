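Package: plastmark
Title: Marker Discovery from Whole-Plastome Alignments
Version: 0.1.0
Authors@R:
    person("Plastmark", "Developers", email = "plastmark@example.org",
           role = c("aut", "cre"))
Description: Comparative marker discovery for chloroplast genomes. From a
    multiple alignment of colinear plastomes the package derives a best-base
    and an ambiguous (perfect-conservation) consensus track, detects
    polymorphic di- and tri-nucleotide microsatellites, scans for
    hypervariable fixed-width barcode blocks at genus or family stringency,
    designs PCR primer pairs confined to perfectly conserved sequence, and
    builds a bootstrap-supported Kimura two-parameter neighbor-joining tree.
    A seeded plastome-family simulator with planted, ground-truthed marker
    structure makes every stage verifiable without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    ape,
    Biostrings,
    jsonlite,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
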