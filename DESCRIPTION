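Package: pitnet
Title: Gap-Junction-Coupled Networks of Spiking and Bursting Pituitary Cells
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Simulation and analysis of small electrically coupled networks of
    pituitary lactotroph model cells. Implements the conductance-based single-cell
    model with delayed-rectifier, L-type Ca2+, BK, SK and leak currents, ohmic
    gap-junction coupling, and a calcium-driven sigmoidal secretion readout;
    fixed-step Runge-Kutta network integration (compiled); random-walk structural
    network generation with burster/spiker labelling and homophily statistics;
    hysteresis-based burst/spike event detection and synchrony measures; algebraic
    fast/slow analysis of the spiker subsystem (critical manifold, fold curve,
    desingularized reduced flow, folded-node location, eigenvalue ratio and
    secondary-canard count); and placement-sweep pipelines relating burster
    homophily to network-averaged secretion.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    jsonlite,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
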