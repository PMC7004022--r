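Package: krigwater
Title: Kriging-Based Flexible, Polarizable Water Model with Multipolar
    Electrostatics
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Builds machine-learned force-field models of the water monomer
    and runs molecular dynamics of water clusters with them. Monomer
    configurations are generated by stochastic normal-mode sampling, labelled
    with per-atom energies and real spherical multipole moments by an
    analytic surrogate for a quantum-topological partitioning pipeline,
    filtered on net-charge and integration-error quality criteria, and
    mapped to internal-coordinate features by kriging (Gaussian process
    regression) with hyperparameters fitted by particle swarm optimisation of
    the concentrated log-likelihood. Trained models drive NVT/NVE molecular
    dynamics of nonperiodic water clusters with kriged intramolecular
    energies and forces, polarizable multipolar electrostatics truncated at
    interaction rank L = 1, 2 or 3, and shifted Lennard-Jones dispersion.
    Analysis tools compute radial distribution functions, internal-coordinate
    distributions, bond-scan validation curves and model-quality tables.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp,
    jsonlite,
    stats,
    utils
LinkingTo:
    Rcpp,
    RcppArmadillo
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
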