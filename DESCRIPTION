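Package: smgosteo
Title: Downstream Analysis of Osteogenic Differentiation Under Simulated Microgravity
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Statistical pipeline for label-free data-independent-acquisition
    proteomics of bone marrow stromal cells differentiating under simulated
    microgravity: reference-ratio preprocessing, valid-value filtering,
    downshifted-Gaussian imputation of left-censored missing values, one-way
    ANOVA with permutation-based false-discovery-rate control, Tukey HSD
    post-hoc calls and trend classification of differentially abundant
    protein groups. Also provides a concentric radial-belt algorithm for
    quantifying cytoskeleton distribution in fluorescence images from the
    centrosome to the cell edge, relative qPCR quantification (2^-ddCt),
    linear standard-curve calibration for enzymatic and immunoenzymatic
    assays, crystal-size statistics, hypergeometric over-representation
    analysis, and a synthetic-data module that generates every input with
    known ground truth.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    graphics,
    tools,
    withr,
    jsonlite,
    yaml,
    tiff,
    png
Suggests:
    testthat (>= 3.0.0),
    pracma,
    EBImage
Config/testthat/edition: 3
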