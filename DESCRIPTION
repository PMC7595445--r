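Package: invertype
Title: Detect, Genotype, and Localize Chromosomal Inversions from SNP Data
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Principal component analysis of one-hot encoded SNP genotype
    matrices for detecting polymorphic chromosomal inversions, inferring
    per-sample inversion karyotypes by k-means clustering in PC space, and
    localizing inversion boundaries through per-SNP multinomial
    logistic-regression likelihood-ratio tests against PC coordinates or
    cluster labels. Includes a diploid genotype simulator with known
    inversion karyotypes and optional two-population structure
    (Balding-Nichols drift) for validating every stage of the workflow,
    plus Manhattan and PCA scatter plots and a command-line interface.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    Matrix,
    purrr,
    Rcpp,
    readr,
    rlang,
    stats,
    tibble,
    vcfR
LinkingTo:
    Rcpp,
    RcppArmadillo
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
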