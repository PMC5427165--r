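Package: appscreen
Title: High-Content siRNA Screen Analysis for APP Metabolism
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: An end-to-end analysis pipeline for genome-wide, high-content
    RNAi screens of amyloid precursor protein (APP) metabolism read out by a
    dual-fluorescence (mCherry/YFP) reporter. Provides synthetic multi-channel
    well-image and intensity-level screen simulators with exported ground
    truth, Hoechst-seeded nucleus and cell segmentation with per-cell
    cytoplasmic intensity quantification, within-plate fold-change
    normalization against non-targeting controls, strictly standardized mean
    difference (SSMD) plate quality control, two-tailed percentile hit calling
    over replicate screens, replicate-robustness reporting, and
    cross-referencing of hits against GWAS-locus candidate genes with a
    gene-wide Bonferroni filter.
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
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    tiff,
    tools,
    utils,
    withr,
    yaml
Suggests:
    jsonlite,
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
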