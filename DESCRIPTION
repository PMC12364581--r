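Package: togglen
Title: Dynamics and Combinatorics of Mutually Repressive Gene Regulatory
    Networks
Version: 1.0.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Simulation and combinatorial analysis of multi-node mutually
    repressive ("toggle-n") gene regulatory networks. Provides asynchronous
    Boolean simulation under the Ising update formalism with steady-state
    detection and k-high frequency statistics, a multi-level extension of
    the formalism for networks of transcription-factor teams, generators
    for toggle, impurity, team and randomly embedded network families,
    edge-weight and cytokine-signalling interventions with 2-D threshold
    scans, and exact enumeration of the monotone Boolean functions
    compatible with a toggle network together with the counts of function
    tuples supporting each k-high fixed point. Includes a T-helper-cell
    differentiation case study network.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    igraph,
    jsonlite,
    Rcpp,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
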