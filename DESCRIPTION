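Package: attractornet
Title: Attractor Metabolic Networks: Simulation, Inverse-Ising Learning and
    Hopfield Memory Readout
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Tools for studying associative memory in dissipative metabolic
    networks. Simulates deterministic catalytic dynamics of coupled
    multienzymatic subsystems driven by substrate fluxes and allosteric or
    covalent regulatory signals, binarizes the emergent activity, and fits an
    equivalent Boltzmann (pairwise Ising) model by mean-field plus
    linear-response inverse inference, with an exact-enumeration Boltzmann
    machine as a small-network oracle. Mean-field Shannon entropy and energy
    summarize the fitted model. Candidate stored memories are read out from
    the learned couplings by least-squares fit to a Hebbian encoding
    (exhaustive search for one pattern, a genetic algorithm for two) and
    validated as attractors of the equivalent Hopfield network under Glauber
    dynamics, including Monte-Carlo estimation of the classical storage
    capacity.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    jsonlite,
    Rcpp,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
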