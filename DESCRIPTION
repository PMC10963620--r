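Package: psdscreen
Title: Longitudinal High-Content Quantification of PSD95-eGFP Synaptic Puncta
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Automated image analysis for longitudinal high-content synapse
    screening in two-channel fluorescence microscopy. Builds a neurite mask
    from a cell-fill (mCherry) channel with somatic regions excluded,
    detects PSD95-eGFP puncta by Gaussian/top-hat enhancement with triangle
    auto-thresholding, applies object-level quality filters (elongation,
    mask overlap, size, local signal-to-noise ratio), pairs puncta counts
    across imaging timepoints to compute percent synapse change per region
    of interest, enforces ROI- and plate-level quality-control gates,
    removes aberrant ROIs with an FDR-based robust outlier test, and
    reports assay-quality statistics (SSMD). Includes a seeded synthetic
    scene and plate generator with ground truth so that every pipeline
    stage is testable without microscope data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    igraph,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    tiff,
    utils,
    yaml
Suggests:
    jsonlite,
    knitr,
    optparse,
    rmarkdown,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
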