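Package: hiermotion
Title: Hierarchical Causal Inference Models of Motion Perception
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Tools for modelling human motion perception as hierarchical
    Bayesian causal inference. Visual elements are grouped into nested
    reference frames (grouping trees); a mixture prior on relative velocity
    with a delta component at zero (stationarity from friction) and a slow
    speed Gaussian component induces a posterior over causal structures that
    is an exact mixture of Gaussians over perceived velocity. The package
    enumerates causal structures, computes percept mixtures, maps them to von
    Mises direction mixtures, predicts full response distributions for
    direction-report psychophysics via Gauss-Hermite quadrature under four
    readout strategies (model averaging, model selection, structure sampling,
    posterior sampling), simulates synthetic observers, and fits model
    parameters to trial data by maximum likelihood or MCMC with AIC model
    comparison.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    graphics,
    jsonlite,
    pracma
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
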