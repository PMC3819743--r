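Package: triplexquant
Title: Triplex Stable-Isotope Dimethyl Labeling Phosphoproteomics Quantification
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Quantitative phosphoproteomics toolkit for triplex stable-isotope
    dimethyl labeling experiments. Provides in silico tryptic digestion and
    monoisotopic mass arithmetic for light/intermediate/heavy dimethyl
    channels, matching of co-eluting channel features into quantifiable
    triplets, LOWESS (MA-trend) normalization of peptide ratios with
    protein-level roll-up and significance testing, phosphosite localization
    by the normalized Mascot delta score (nMD-score) with calibration of the
    score threshold at a target false localization rate, kinase
    consensus-motif scanning of accepted phosphosites, and position weight
    matrix scanning of promoter sequences. A synthetic-data generator
    emulates a two-triplex, five-timepoint induction design with known
    ground truth so every pipeline stage is testable end to end.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Biostrings,
    jsonlite,
    stats,
    tools,
    utils,
    yaml
Suggests:
    limma,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
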