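Package: latentpan
Title: Hierarchical Latent-Variable Testing for Gene Presence in Pangenomes
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tests whether gene presence in bacterial (pan)genomes is associated
    with covariates of interest while adjusting for genome-quality variables
    (e.g., mean coverage, CheckM completion) that drive non-detection of truly
    present genes. Gene presence is modeled as a latent Bernoulli variable with
    a logistic dependence on covariates; detection of a present gene follows a
    monotone non-decreasing curve in genome quality, estimated either as a
    non-negative I-spline combination or by isotonic regression. Parameters are
    estimated by an EM algorithm with a Firth-type penalty on the regression
    coefficients, and hypotheses of the form A beta = c are tested with an
    asymptotic chi-squared likelihood-ratio test or a permutation test suited to
    small sample sizes. Includes logistic-regression baselines (LRT and Rao
    score test), Benjamini-Hochberg FDR adjustment across genes, an
    epsilon-sensitivity sweep, and a simulation framework for type-1-error and
    power studies.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    splines,
    parallel,
    tools,
    jsonlite,
    optparse
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
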