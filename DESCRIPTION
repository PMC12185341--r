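Package: aisquant
Title: Quantitative Profilometry and Classification of Axon Initial Segment Fluorescence
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for quantitative analysis of axon-initial-segment (AIS) and
    soma fluorescence in neuronal microscopy: sum projection of confocal
    z-stacks, threshold-based soma regions of interest, wide line-profile
    extraction along annotated AIS and neurite paths, AIS length and AIS/soma
    polarity measures; discrete-Fourier-transform descriptors of calibrated
    intensity traces and Haralick-family texture features (gray-level
    co-occurrence, dependence and size-zone matrices) of masked soma regions;
    a repeated-holdout random-forest harness for cell-level diagnosis and
    treatment classification; hierarchical group statistics for
    cells-within-subjects designs (nested t-test, split-plot two-way mixed
    ANOVA, Dunnett and Sidak multiple comparisons); and a seeded synthetic
    cohort generator so every stage is testable without imaging data.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    dplyr,
    tidyr,
    purrr,
    tibble,
    rlang,
    ggplot2,
    readr,
    jsonlite,
    generics,
    randomForest,
    mvtnorm,
    e1071,
    tiff,
    EBImage,
    stats,
    tools,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
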