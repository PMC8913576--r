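Package: circpepscan
Title: Scanning Circular RNAs for Peptide-Coding Potential
Version: 0.1.0
Authors@R:
    person("circpepscan", "developers", email = "circpepscan@posteo.net",
           role = c("aut", "cre"))
Description: Detects open reading frames on circular RNA sequences,
    including back-splice-junction-wrapping and rolling-circle reading
    frames, excludes infinite (stop-free) ORFs, and applies candidate
    filters for peptide-coding potential: junction spanning, minimum
    peptide length, bounded base reuse (overlay), database coding flags,
    a differential-expression gate, and uniqueness of the predicted
    peptide against the host-gene linear protein. Produces in-silico
    tryptic evidence peptides with monoisotopic and average masses and a
    protein-FASTA search database for LC-MS/MS verification, plus
    synthetic fixtures with planted ground truth for end-to-end testing.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Biostrings,
    jsonlite,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
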