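Package: absorbcell
Title: Traceable Cell Viability from Absorbance Microscopy
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Converts brightfield micrograph triplets (sample, blank and dark
    references) into quantitative absorbance images, quantifies intracellular
    trypan blue per cell in moles and molarity via the Beer-Lambert law,
    corrects for background dye absorbance and cell-edge scattering, and
    classifies cells live/dead from per-cell dye-content histograms. Includes
    a synthetic phantom generator that emulates the standard live/dead
    treatment designs with known ground truth, so the whole pipeline is
    testable without microscope data.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    mclust,
    minpack.lm,
    purrr,
    Rcpp,
    rlang,
    stats,
    tibble,
    tidyr,
    tiff,
    utils,
    yaml
LinkingTo:
    Rcpp
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
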