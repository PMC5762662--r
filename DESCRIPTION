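Package: traitflux
Title: Decomposing Community Trait Change into Species Turnover and
    Intraspecific Variation
Version: 0.1.0
Authors@R:
    person("traitflux", "maintainers", email = "maintainers@traitflux.org",
           role = c("aut", "cre"))
Description: Tools for partitioning change in community-level functional
    trait values along environmental gradients into species-turnover and
    intraspecific components.  Implements specific and fixed
    community-weighted means and their sum-of-squares decomposition,
    Hill-Smith ordination of mixed quantitative/categorical trait tables,
    RLQ and partial RLQ cross-covariance analysis of trait-environment
    relationships, quasi-binomial models for community proportions of
    categorical traits, and linear mixed models for individual-scale trait
    responses to ontogeny and light.  Ships a synthetic sapling-community
    generator with stored ground truth so every stage has a
    parameter-recovery test, plus a pipeline runner and command-line
    interface.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    jsonlite,
    lme4
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse
Config/testthat/edition: 3
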