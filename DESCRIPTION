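Package: igsca
Title: Imaging Genetics Generalized Structured Component Analysis
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Component-based structural equation modelling for imaging
    genetics. Builds gene and brain region-of-interest (ROI) composites from
    SNP dosages and relative ROI volumes, estimates ridge-regularized
    structural paths between genes, potentially traumatic events (PTE), their
    interactions, ROI volumes, and PTSD symptom severity by alternating least
    squares, tunes the ridge penalty by repeated k-fold cross-validation,
    quantifies uncertainty with bootstrap standard errors and percentile
    confidence intervals (including mediation products along
    gene-ROI-outcome chains), and reports overall fit (FIT, GFI, SRMR).
    Includes a synthetic-data generator that emulates the study design's
    genotype frequencies, ROI volume scales, and planted structural effects
    for end-to-end testing and parameter-recovery studies.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    methods,
    stats,
    utils,
    jsonlite,
    MASS,
    e1071,
    S4Vectors,
    SummarizedExperiment
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
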