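Package: dendromod
Title: Context-Dependent Dendritic Modulation of Feedforward Networks
Version: 0.1.0
Authors@R:
    person("dendromod", "maintainers", email = "maintainers@example.org",
           role = c("aut", "cre"))
Description: Tools to study how context-dependent dendritic modulation can
    reshape feedforward sensory processing. Provides gain-modulated
    feedforward networks with task-specific parameters for multitask and
    transfer learning; unsupervised feedforward weight matrices aligned to
    difference vectors between data samples (principal components, sparse
    dictionary learning, penalized matrix decomposition, random
    projections); greedy layer-wise task-modulated contrastive learning;
    a spiking network of simplified neurons with NMDA-like dendritic
    compartments trained by an online error-modulated Hebbian rule;
    input-output curve characterization with joint rectified-linear fits;
    and synthetic data generators so that every analysis runs without
    external downloads.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    jsonlite,
    Rcpp,
    stats,
    tools,
    utils
LinkingTo:
    Rcpp
Suggests:
    withr,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
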