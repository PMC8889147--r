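Package: steatoscreen
Title: Signature-Reversion Drug Repositioning and In Vitro Screening
    Analytics for Hepatic Steatosis
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: An integrated computational drug-repositioning pipeline for
    non-alcoholic fatty liver disease (NAFLD), from gene-level differential
    expression with empirical-Bayes moderated t-statistics, through
    directional gene-set analysis with multi-method consensus ranking, to
    Kolmogorov-Smirnov connectivity scoring of disease signatures against a
    compound-signature library, pathway-group intersection and candidate
    ranking with toxicity exclusion. The experimental arm is covered by
    lipid-droplet image quantification, ROS and viability analytics with
    four-parameter logistic dose-response fitting and IC10 extrapolation,
    ANOVA/Tukey group comparison, and proteomic mode-of-action clustering.
    A synthetic-universe generator produces every input with known ground
    truth so the whole pipeline is testable offline.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    jsonlite,
    yaml,
    rlang,
    minpack.lm,
    EBImage,
    tiff,
    mclust,
    cluster
Suggests:
    limma,
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
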