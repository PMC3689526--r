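Package: serialx
Title: Serial Femtosecond Crystallography Data Processing
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A desk-scale processing pipeline for serial femtosecond
    crystallography (SFX) still diffraction data: detector-frame correction and
    pixel-wise median background subtraction, Bragg-peak finding with local
    signal-to-noise screening and hit classification, known-cell
    reciprocal-vector autoindexing by a projected-lattice spectral search,
    three-ring summation integration with a propagated error model, point-group
    machinery for merohedral indexing ambiguities (coset decomposition and
    apparent merging symmetry), Monte-Carlo intensity merging with the R_split
    half-data-set statistic, and a reflection-partiality simulator for studying
    how spectral bandwidth and beam convergence accelerate Monte-Carlo
    convergence. Includes a synthetic-frame generator so the whole pipeline is
    testable end to end without experimental data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    tibble,
    dplyr,
    purrr,
    rlang,
    ggplot2,
    generics,
    jsonlite,
    stats,
    utils
LinkingTo: Rcpp
Suggests: testthat (>= 3.0.0)
Config/testthat/edition: 3
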