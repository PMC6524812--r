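Package: leksim
Title: Virtual-Ecologist Simulation and Bias Evaluation for Lek-Count
    Monitoring
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: An individual-based demographic simulator for lekking grouse
    populations (parameterised for the lesser prairie-chicken), an
    observation layer with age- and sex-specific or density-dependent lek
    attendance and imperfect detection, Bayesian state-space and N-mixture
    estimators of the long-term population growth rate, and a
    virtual-ecologist harness that quantifies the bias of lek-count
    monitoring designs against the simulated truth.
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
    purrr,
    Rcpp,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    yaml
LinkingTo:
    Rcpp
Suggests:
    coda,
    jsonlite,
    optparse,
    rjags,
    withr,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
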