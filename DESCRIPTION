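Package: mpxdesign
Title: Multiplex PCR Primer Design by Amplicon Tiling for Targeted Sequencing
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Designs multiplex PCR (MPCR) primer panels that tile a continuous
    genomic region with overlapping amplicons for targeted next-generation
    sequencing. Primer candidates are screened with nearest-neighbor duplex
    thermodynamics (melting temperature, hairpin, homodimer and heterodimer
    free energies), GC content, homopolymer and 3'-variant rules, and an
    optional BLAST or exact-match specificity check. A time-limited
    depth-first search places amplicons of 300-500 bases so that adjacent
    products overlap, products are assigned round-robin to two or more test
    tubes, and all primers sharing a tube are pairwise compatible (a clique
    in the primer compatibility graph). Includes a seeded synthetic-region
    generator, an exhaustive small-scale tiling enumerator used as a test
    oracle, a standalone solution verifier, reporting to BED/TSV, and a
    benchmark harness with Fisher's exact comparisons of success rates.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.2)
Imports:
    methods,
    stats,
    utils,
    Biostrings,
    GenomicRanges,
    rtracklayer
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    optparse
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
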