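Package: SoilMnOx
Title: Community Analysis of Soil Mn(II)-Oxidizing Bacteria from Activity
    Assays, ARDRA, DGGE Fingerprints and 16S Phylotyping
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: An integrated pipeline for characterizing manganese(II)-oxidizing
    bacterial communities in stratified soils. Converts leucoberbelin-blue
    colorimetric readings to MnO2-equivalent activities and cross-tabulates
    activity categories by soil horizon; performs in-silico amplified
    ribosomal DNA restriction analysis (ARDRA) with HaeIII and Sau3AI and
    two-stage pattern grouping; calls bands from 1-D densitometric DGGE lane
    profiles with a 1% relative-peak-height detection rule, computes Shannon
    diversity and a band-pattern lane distance, and ordinates lanes by
    classical and non-metric multidimensional scaling; clusters 16S rRNA
    sequences into phylotypes at a 3% divergence threshold and builds
    Kimura two-parameter neighbor-joining trees with bootstrap supports.
    A synthetic-data module generates random trees, K2P-evolved alignments,
    noisy densitometric lanes and per-horizon activity tables so the whole
    pipeline is testable without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.3)
Imports:
    methods,
    stats,
    utils,
    Biostrings,
    ape,
    vegan,
    yaml
Suggests:
    testthat (>= 3.0.0),
    phangorn,
    jsonlite
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
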