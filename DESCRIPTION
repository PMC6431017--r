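Package: bnpower
Title: Bayesian-Network Power Analysis for Exposure-Response Study Design
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Simulation-based power analysis for exposure-response studies
    using a discrete Bayesian network. An eight-node network links latent
    measurement accuracies, true and measured exposure and response, and the
    strength of the exposure-response relationship; synthetic studies are
    generated by seeded ancestral sampling under clamped scenarios, the
    posterior over the strength of relationship is updated case by case via
    Bayes factors (with an exact batch oracle), and replicate trials yield
    the sample size required to identify the true relationship at a given
    posterior threshold under each level of measurement accuracy.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
Imports:
    jsonlite,
    optparse,
    stats,
    utils,
    graphics,
    grDevices,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
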