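Package: stopsignal
Title: Collective Foraging Dynamics with Positive and Negative Social Feedback
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Mean-field and exact stochastic simulation of collective foraging
    regulation in social-insect colonies. Forager populations allocate
    themselves across forage patches through independent discovery, spontaneous
    abandonment, recruitment (positive social feedback) and stop signalling
    (negative social feedback, self-inhibition). The package compiles three
    model variants (positive feedback only, positive plus negative feedback,
    and an asocial baseline) into a common mass-action reaction system, solves
    the infinite-population ordinary differential equation limit with a
    stiff-capable integrator, simulates finite populations exactly with
    Gillespie's direct-method stochastic simulation algorithm, and provides
    the readouts needed to study quality-proportional patch allocation:
    distance from the target distribution, ensemble variance, convergence
    times, fixed points with stability analysis, and the speed-robustness
    trade-off controlled by the stop-signal strength.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.0)
Imports:
    Rcpp,
    deSolve,
    jsonlite,
    stats,
    tools,
    utils,
    withr,
    yaml
LinkingTo:
    Rcpp
Suggests:
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
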