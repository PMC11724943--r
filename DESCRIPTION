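Package: minibarc
Title: Mitochondrial Mini-Barcode Design and Amplicon Metabarcoding
Version: 0.1.0
Authors@R: person("Barcode", "Maintainers", email = "maintainers@example.org",
    role = c("aut", "cre"))
Description: Toolkit for developing short ("mini") DNA barcodes from panels of
    closely related mitochondrial genomes and applying them to mixed samples.
    Scans per-gene multiple alignments for nucleotide diversity (pi) with a
    sliding window, locates perfectly conserved primer-anchor windows flanking
    hypervariable cores, enumerates and ranks primer pairs under amplicon-length
    and thermodynamic constraints, validates candidates by mismatch-tolerant
    in-silico PCR, and classifies amplicon reads from mixtures into species
    composition tables via dereplication, lite denoising, and best-hit identity
    against a reference amplicon panel. Includes a fully specified synthetic
    data generator (planted conserved anchors, tunable divergence, error-bearing
    read mixtures with known weights) so every stage is testable offline.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    Biostrings,
    S4Vectors,
    jsonlite,
    stats,
    utils,
    methods
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
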