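Package: snappcheck
Title: Posterior Predictive Model Checks for Multispecies Coalescent
    Analyses of SNP Data
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Posterior predictive simulation for checking the fit of the
    multispecies coalescent model to biallelic SNP data analysed with
    SNAPP-style Bayesian species-tree inference.  Given a posterior
    distribution of species trees and a trace log, the package simulates
    posterior predictive SNP datasets under the multispecies coalescent
    with a native structured-coalescent simulator (optionally with a
    secondary-contact migration window), computes data-based (pairwise
    Hudson F_ST mean, range and outlier test) and inference-based
    (Robinson-Foulds and Kuhner-Felsenstein tree distances, tree
    likelihood mean and standard deviation) summary statistics, and flags
    model violations such as gene flow via two-tailed posterior
    predictive p-values.  Includes a simulation-study harness with
    confusion-matrix and Matthews-correlation-coefficient evaluation, a
    synthetic posterior generator for testing without an external
    inference run, and SNAPP-compatible readers and writers.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    ape,
    phangorn,
    xml2,
    jsonlite,
    stats,
    utils,
    grDevices,
    parallel
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
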