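Package: vocalarm
Title: Roughness, Classification, and Perceptual Decision Analysis of Human Scream Calls
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for the psychoacoustic and perceptual-decision analysis of
    human scream-like vocalizations. Computes modulation power spectra (MPS)
    from log-frequency spectrograms and extracts temporal-modulation
    "roughness" band power; forms group MPS difference maps with a
    label-shuffling permutation null; classifies vocalizations from acoustic
    feature tables with a cross-validated polynomial-kernel support vector
    machine, including cross-corpus classification; searches exhaustively over
    all admissible alarm/non-alarm categorizations of six scream types by
    repeated-measures ANOVA; and scores 7-alternative and 2-alternative
    forced-choice behavioral logs (confusion matrices, false-alarm rates,
    multi-class d-prime, pairwise discrimination with FDR correction). A
    synthetic-data module generates audio corpora, feature tables, rating
    tables, and trial logs with planted structure so the full pipeline is
    testable end to end without external recordings.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    tools,
    e1071,
    jsonlite,
    yaml,
    withr
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
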