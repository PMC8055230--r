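Package: clonetrend
Title: Clonal Deconvolution of Longitudinal Tumour Sequencing Data with
    Gaussian Process Priors
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Clusters somatic mutations from longitudinally collected tumour
    samples by cancer-cell fraction (CCF) using a truncated Dirichlet-process
    mixture, models each cluster's CCF as a continuous function of time via
    Gaussian-process priors on logit-CCF trajectories, and fits by
    stochastic-gradient variational inference. Includes purity and copy-number
    correction of variant allele fractions, binomial and beta-binomial read
    count models, ELBO-based model comparison across a registry of prior
    families and kernels, clustering-agreement metrics, a synthetic-data
    simulator with known clonal structure, and tidy reporting and plotting of
    cluster trajectories with credible bands.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils
Suggests:
    mclust,
    pracma,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
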