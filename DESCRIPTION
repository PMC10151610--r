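Package: reactoracle
Title: Bayesian Oracle for Combinatorial Chemical Reactivity
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Probabilistic interpretation of combinatorial chemical
    reactivity observations. Compounds in an enumerable chemical space are
    modelled as carrying latent abstract properties to continuous degrees;
    symmetric reactivity tensors over property combinations generate binary
    or multi-bit reactivity outcomes through a noisy-OR relational
    likelihood with an optional emission map onto chromatogram-derived bit
    vectors. Posteriors are fitted by Hamiltonian Monte Carlo with analytic
    gradients; a brute-force grid integrator serves as an independent
    oracle. On top of the generative model the package quantifies per
    observation surprise (prior, online and final-posterior negative log
    predictive likelihood), ranks unexplored experiments by expected
    disruption, shortlists anomalies, registers rival theories under
    content-addressed identifiers and compares them through posterior
    mixture weights. Synthetic chemical spaces with planted reaction rules
    (acid-base, Diels-Alder, Passerini, and a panel of named reactions
    encoded as 8-bit reactivity vectors) and a chromatogram-peak vectorizer
    generate all data needed to exercise the system.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp,
    jsonlite,
    stats,
    utils,
    tools
LinkingTo: Rcpp
Suggests:
    ChemmineOB,
    pROC,
    optparse,
    yaml,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
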