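Package: proformatch
Title: Proteoform Fragment-Ion Matching and Scoring for Top-Down Mass Spectrometry
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A headless engine for targeted top-down proteomics characterization.
    Defines proteoforms from a ProForma subset (localized, terminal and fixed
    modifications, N-glycans, custom mass shifts), generates theoretical neutral
    monoisotopic fragment masses for the a/b/c/x/y/z ion series, matches
    deconvoluted neutral fragment masses at ppm tolerance with off-by-n isotope
    error recovery, and reports sequence coverage, a Poisson P-score and a
    proteoform characterization score (PCS). Sessions round-trip through a
    versioned XML (.pcml) dialect and a portable share blob, and fragment maps
    export as deterministic self-contained SVG. A synthetic observed-mass
    simulator with ground truth supports end-to-end validation, and a thin
    command-line interface ties the pieces into a shell workflow.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    tibble,
    dplyr,
    purrr,
    tidyr,
    stringr,
    rlang,
    generics,
    ggplot2,
    xml2,
    jsonlite,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
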