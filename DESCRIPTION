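Package: splicescreen
Title: High-Content Screening Analysis of Two-Colour Fluorescent Splicing Reporters
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: An open, scriptable analysis pipeline for high-content screening
    assays built on two-colour (GFP/RFP) fluorescent alternative-splicing
    reporters. From multichannel (Hoechst/GFP/RFP) plate images it segments
    nuclei, measures background-corrected per-cell reporter intensities in
    perinuclear regions of interest, gates transfected cells against
    untransfected control wells, classifies each cell by its G/R intensity
    ratio into exon-included (RFP), exon-skipped (GFP) or dual populations,
    summarises wells, scores plate quality with the Z-prime factor, and
    quantifies dose-response of splice-modulating treatments. A companion
    densitometry module performs ladder-calibrated band quantification of
    semiquantitative RT-PCR lane profiles with housekeeping-gene
    normalisation. A synthetic plate generator with exact per-cell ground
    truth makes every stage testable without an instrument.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    dplyr,
    EBImage,
    generics,
    ggplot2,
    jsonlite,
    pracma,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    tiff,
    utils,
    withr,
    yaml,
    zoo
Suggests:
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
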