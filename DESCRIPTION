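Package: cbgtpolicy
Title: Spiking Cortico-Basal-Ganglia-Thalamic Networks, Dopaminergic
    Plasticity, and Decision-Policy Analysis
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Simulates two-channel spiking cortico-basal-ganglia-thalamic
    (CBGT) networks performing a two-armed bandit task with dopamine-dependent
    eligibility-trace plasticity at corticostriatal synapses, and provides the
    full analysis pipeline for studying how learning shifts decision policies:
    genetic-algorithm sampling of network configurations under physiological
    constraints, drift-diffusion model (DDM) simulation and maximum-likelihood
    fitting of probe behavior, reward-rate/accuracy/speed policy manifolds with
    gradient-alignment scoring, canonical-correlation control ensembles linking
    firing-rate features to DDM parameters, and a least-squares decomposition
    of learning-induced firing-rate changes into control-ensemble drivers.
    Synthetic surrogate generators make every stage testable at desk scale.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    MASS
Config/testthat/edition: 3
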