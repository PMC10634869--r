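Package: midzoner
Title: Quantitative Analysis of Microtubule Overlap and Spindle Dynamics in
    the Anaphase Midzone
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: A toolkit for quantifying the architecture and dynamics of the
    anaphase spindle midzone in early C. elegans embryos. Provides readers
    and a tidy data model for electron-tomography filament tracings (Amira
    SpatialGraph and CSV polylines), pairwise microtubule distance and
    interaction statistics with grid-accelerated exact geometry, microtubule
    polarity mapping from paired second-harmonic-generation and two-photon
    images, a spindle-pole and chromosome tracking pipeline with
    rotation-aligned kymographs and segregation rates, midzone intensity,
    EB-comet and FRAP quantification, single-molecule track summaries, and
    seeded synthetic-data generators with attached ground truth for every
    analysis stage.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    dplyr,
    EBImage,
    generics,
    ggplot2,
    jsonlite,
    minpack.lm,
    purrr,
    Rcpp,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    withr,
    yaml
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    tiff
Config/testthat/edition: 3
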