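Package: neurofret
Title: Ratiometric FRET Quantification and Morphometry for Developing Neurons
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Tools to quantify Rho-GTPase activation from two-channel
    (donor/acceptor) ratiometric FRET confocal z-stacks of single neurons:
    background subtraction, ratio imaging, threshold segmentation,
    depth-normalized 2D density maps, midline-anchored axonal line profiles,
    two-reference profile normalization, Gaussian fitting and area-under-curve
    activation scoring with group aggregation and fold changes. Also counts
    dendritic filopodia (strictly > 1 micron, ipsilateral) on traced SWC
    morphologies, normalizes extracellular-stain intensity timecourses against
    negative-control and wild-type references, and implements the summary-
    statistics hypothesis tests used for such data (Student and Welch t,
    Mann-Whitney U with exact enumeration, one-way ANOVA, Tukey HSD, power
    analysis). A seeded synthetic-data generator produces stacks, morphologies
    and measurement tables with analytic ground truth so every stage of the
    pipeline is verifiable without raw microscopy data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    purrr,
    rlang,
    stats,
    tibble,
    tools,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
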