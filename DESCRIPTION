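Package: poolfish
Title: Hierarchical Multi-Species Distribution Models for Fish in Drying
    River Pools
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "maintainer@example.org")
Description: Fits an integrated hierarchical multi-species distribution
    model for fish assemblages surveyed in disconnected dry-season river
    pools with multiple gear types. Latent species abundance follows a
    Poisson distribution with a Ricker-shaped response to pool depth;
    gear-specific observation sub-models translate catchability into
    capture probability; species-level coefficients are shrunk toward a
    linear function of species mean body length (a fourth-corner trait
    hierarchy); and the detection/non-detection likelihood is marginalized
    over latent abundance. Includes an adaptive MCMC sampler with
    convergence diagnostics, a synthetic survey generator, posterior
    predictive checks, and a management-scenario engine that evaluates
    minimum-depth and percent-reduction water-take rules against species
    distribution-loss objectives.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    coda,
    jsonlite,
    testthat (>= 3.0.0),
    withr,
    yaml
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
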