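Package: cobraAlu
Title: COBRA-Alu Methylation Pattern Simulation, Deconvolution and Case-Control Analysis
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for combined bisulfite restriction analysis (COBRA) of Alu
    retroelement methylation read out on the two-CpG TaqI amplicon. Provides a
    forward model from per-molecule methylation patterns (uCuC, mCuC/uCmC,
    mCmC) to restriction-fragment gel band intensities, the densitometric
    deconvolution recovering pattern percentages from the five bands
    (117/75/74/43/42 bp), a calibrated synthetic cohort generator emulating a
    type 1 diabetes case-control study, and the nonparametric statistical
    layer (median/IQR summaries, Mann-Whitney, Spearman, chi-squared) that
    assembles the study-style report tables.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr,
    jsonlite,
    optparse,
    Biostrings
Config/testthat/edition: 3
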