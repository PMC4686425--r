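Package: punctakit
Title: Quantifying Protein-Body Formation from Gels, Time Courses,
    Sequences and Fluorescence Images
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A tidyverse-native toolkit for quantitative analysis of
    starvation-induced protein agglomeration ("body" formation) in yeast:
    position-weighted densitometry scoring of phosphorylation band shifts
    on SDS-PAGE lanes with two-anchor affine normalization, exponential
    kinetic modelling of body formation and dissociation time courses,
    glutamine/asparagine (Q/N) prion-like motif scanning and composition
    tables, foci counting and channel co-localization on maximum
    projections of 3-D image stacks, and exact 2x2 contingency inference
    by hypergeometric enumeration. A synthetic-data module simulates gel
    lanes, binomial time courses, motif-bearing protein sequences and
    two-channel cell images with known ground truth, so every analysis
    stage is testable end to end.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Biostrings,
    dplyr,
    generics,
    ggplot2,
    minpack.lm,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    tiff,
    withr,
    yaml
Suggests:
    jsonlite,
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
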