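Package: msirep
Title: Microsatellite Instability, Repeat Mutation Spectra, and Transgene
    Integration Analysis for Mismatch-Repair-Deficient Genomes
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for quantifying replication-slippage-driven repeat
    instability in mismatch-repair (MMR) deficient tissue. Implements
    perfect-microsatellite cataloging from a reference genome, per-locus
    allele-length spectra from aligned reads, a Shannon-entropy statistic of
    allelic diversity with motif-by-length stratification and linear
    length trends, baseline-calibrated tumor-only MSI scoring, the rpsL
    reporter-gene mutant-frequency calculus with adenine-run-length
    stratified deletion spectra, somatic-variant filtering with SBS96/ID83
    mutation-matrix classification, chimeric-read-pair detection of a
    plasmid transgene integration site, and seeded synthetic-data
    generators (slippage model, reporter colonies, junction-spanning read
    sets) so every stage is testable without animal sequencing data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    BiocGenerics,
    Biostrings,
    GenomicRanges,
    IRanges,
    methods,
    Rsamtools,
    S4Vectors,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    vcfR,
    withr
Config/testthat/edition: 3
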