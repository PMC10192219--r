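Package: pepTRNAprof
Title: Mass-Spectrometric Profiling of Peptidyl-tRNA Drop-Off
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Tools for profiling peptidyl-tRNA (pep-tRNA) drop-off from
    deconvoluted mass-spectrometry feature lists. Builds N-terminal peptide
    reference mass databases from an ORF set, including initiator-Met-trimmed
    and single amino-acid substitution variants; annotates observed neutral
    masses within a ppm tolerance; classifies nascent peptides as cognate or
    position-typed non-cognate (C0X to C-3X); and computes drop-off
    frequencies, drop-off rates, calibration-curve absolute quantification,
    and codon-level statistics at drop-off sites (TPM-weighted positional
    usage, GC grouping, codon-anticodon mismatch classification, early-ORF
    usage deviation). A seeded synthetic-data generator produces toy ORFeomes
    and ground-truthed mass lists so the whole pipeline is testable without
    external data.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    methods,
    stats,
    utils,
    Biostrings,
    jsonlite
Suggests: testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
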