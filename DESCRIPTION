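Package: antennaquant
Title: Chemosensory Gene Expression Analysis for Moth Antennal Transcriptomes
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "maintainer@example.org")
Description: Tools for analysing the antennal chemosensory gene repertoire of
    moths from qPCR and RNAseq summaries. Implements efficiency-corrected
    delta-Ct relative quantification (per-sample amplification efficiencies,
    E_MAX Ct correction, housekeeping normalization factor, replicate
    aggregation) with Welch-test sex-bias calling; a window-of-linearity
    amplification-efficiency estimator for raw fluorescence curves; FPKM
    detection and qPCR/RNAseq concordance summaries; rule-based classification
    of odorant binding proteins by their cysteine skeleton (classic, minus-C,
    plus-C) and pheromone-receptor-clade 'PWE' motif screening with global
    alignment percent identity; and seeded synthetic-data generators
    (amplification curves, Ct/efficiency well tables, FPKM tables, OBP-like
    sequences) with recorded ground truth for parameter-recovery testing.
    Ships the published expression tables for the lightbrown apple moth
    (Epiphyas postvittana) antennal repertoire as packaged fixtures.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    Biostrings
Suggests:
    testthat (>= 3.0.0),
    withr,
    jsonlite
Config/testthat/edition: 3
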