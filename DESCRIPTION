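Package: phorep
Title: Phosphatase Repertoire Annotation, Regulatory Motif Scanning and
    Phosphatogenesis Geochemistry
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools to characterise the non-specific phosphatase repertoire of
    bacterial genomes and its link to calcium-phosphate biomineralization
    (phosphatogenesis). Implements profile (PSSM) based family annotation with
    a mutual-coverage redundancy rule and an all-profiles membership rule,
    transcription-factor binding-site scanning with exact p-values under an
    order-1 Markov background, sequence-derived protein features (molecular
    weight, theoretical pI, Tat signal motifs), structural active-site
    detection and Shrake-Rupley solvent accessibility, hydroxyapatite
    saturation-index geochemistry with Davies activity corrections,
    absorbance-based hydrolysis kinetics, and multi-genome repertoire survey
    statistics. Seeded synthetic-data generators make every stage testable
    without external downloads.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    Biostrings,
    bio3d,
    dplyr,
    generics,
    ggplot2,
    purrr,
    readr,
    rlang,
    stats,
    stringr,
    tibble,
    tidyr,
    utils
Suggests:
    jsonlite,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
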