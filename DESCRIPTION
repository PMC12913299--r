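Package: diffusionlens
Title: Diffusion Lens Model of Multiple-Cue Probability Learning
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for modelling dynamic cognitive adjustment in multiple-cue
    probability learning (weather-prediction-style) tasks with a two-level
    stochastic process: trial-wise binary choices and response times follow a
    four-parameter Wiener diffusion process whose drift rate is a linear
    function of the ecological validity of the presented cue pattern and whose
    non-decision time grows linearly with the number of presented cues, while
    the drift sensitivity, boundary separation and base non-decision time
    evolve across trials as Gaussian random walks. Includes the canonical
    14-pattern four-cue learning environment, exact Wiener first-passage-time
    densities, forward simulation of participants and experiments, bootstrap
    particle filtering and particle-marginal Metropolis-Hastings inference,
    posterior re-simulation, and the classical lens-model-equation and
    take-the-best baselines.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp,
    stats,
    utils,
    yaml
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr,
    jsonlite
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
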