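Package: morphoplast
Title: Landmark-Based Analysis of Predator-Induced Shape Plasticity
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for landmark-based geometric morphometrics of inducible
    morphological defences along an ordered predation-risk gradient.
    Implements Generalized Procrustes superimposition with digitisation
    repeatability, Procrustes ANOVA with significance by residual
    randomization in a permutation procedure (RRPP), phenotypic trajectory
    analysis (path distance, direction and trajectory shape with pairwise
    permutation tests), covariance-ratio modularity and two-block partial
    least squares integration tests over named landmark partitions,
    principal component analysis of shape with thin-plate-spline
    deformation grids, and a synthetic landmark-data generator that
    emulates a factorial clone-by-instar-by-risk design with modular
    block covariance so the whole pipeline can be exercised without
    external data. Results are tibble-friendly with broom-style tidy()
    and glance() methods and ggplot2 autoplot() visualisations.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils
Suggests:
    Matrix,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
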