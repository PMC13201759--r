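Package: msimclink
Title: Co-Registration and Spatial Association Modeling for MALDI-MSI and
    Imaging Mass Cytometry
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Links MALDI mass spectrometry imaging (MSI) pixel grids to
    imaging mass cytometry (IMC) single-cell data through a chain of
    brightfield microscopy images. Provides MSI spectrum preprocessing
    (TIC normalization, reference alignment, peak binning), IMC pixel and
    cell-table cleanup, ablation-mark grid detection and point-grid
    matching with coherent point drift, affine and b-spline slide
    registration with composable transform chains, registration quality
    control (median landmark distance, DICE, automatic landmarks,
    grid-artifact suppression), exact cell-to-pixel polygon overlap
    integration, simultaneous autoregressive (spatial lag) pixel models
    with a weighted second-stage across samples, compositional
    pivot-coordinate models, tissue-domain assignment, and a synthetic
    tissue simulator used as the ground-truth engine for every stage.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    dplyr,
    EBImage,
    generics,
    ggplot2,
    igraph,
    jsonlite,
    lme4,
    Matrix,
    methods,
    purrr,
    rlang,
    stats,
    tibble,
    tidyr,
    tools,
    utils,
    xml2,
    yaml
Suggests:
    png,
    optparse,
    tiff,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
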