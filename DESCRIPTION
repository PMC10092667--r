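Package: seabirdDD
Title: Density Dependence in Colonial Seabird Populations from Count Time Series
Version: 0.1.0
Authors@R:
    person("seabirdDD", "Maintainers", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Two-stage Bayesian analysis of density dependence in colonial
    seabird population dynamics. Stage one fits discrete-time stochastic
    Ricker state-space models (with and without direct and delayed density
    dependence) to annual colony count time series by MCMC, treating
    observation error as Poisson, missing counts as latent variables and
    individuals-to-pairs conversion factors as latent annual adjustments.
    Model support is compared by the deviance information criterion and fit
    is checked with posterior predictive Bayesian p-values. Stage two relates
    the estimated strength of density dependence to temporal variation in
    climate and spatiotemporal variation in prey resources, computed from
    gridded monthly environmental fields within species-specific foraging
    buffers, via a Bayesian errors-in-variables regression. A synthetic-data
    module generates count series, conversion factors, environmental grids
    and stage-two datasets with known ground truth so the whole pipeline is
    testable without access to the underlying monitoring data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Rcpp,
    mgcv,
    jsonlite,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
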