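Package: influscreen
Title: Directional Genetic Interaction Networks from Multi-Phenotype
    Double-Knockdown Screens
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Combined analysis of pleiotropy and epistasis for all-pairs
    double-knockdown screens measuring several correlated quantitative
    phenotypes. Phenotypes are decomposed into orthogonal eigentraits by
    singular value decomposition; per-eigentrait pairwise regression
    interaction coefficients are reparametrized into directed
    knockdown-to-knockdown influence coefficients with delta-method
    standard errors; significance is assessed by tandem genotype
    permutations with extreme-value calibration of single-locus scans and
    free step-down maxT familywise error control; significant directed
    influences and knockdown-to-phenotype effects are assembled into a
    genetic-interaction network with rule-based pathway-role inference.
    Includes a generative simulator of all-pairs screens with planted
    directional influences.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Rcpp,
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
    utils,
    yaml
LinkingTo:
    Rcpp,
    RcppArmadillo
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
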