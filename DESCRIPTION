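Package: hhrepro
Title: Replicability-Controlled Simulation of a Depressing Hodgkin-Huxley
    Network
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Deterministic simulator for a small all-to-all network of
    Hodgkin-Huxley-type neurons with activity-dependent synaptic depression,
    built so that every floating-point source of numerical non-replicability
    is an explicit, testable configuration axis.  Presynaptic conductance
    sums can be accumulated naively, with Kahan compensation, or with a
    correctly rounded order-invariant superaccumulator; arithmetic can run in
    IEEE binary64 or in an in-package decimal floating-point backend with a
    configurable number of significant digits; all constants are initialized
    from decimal literal strings; and the fixed-step fourth-order Runge-Kutta
    integrator pins its operation order.  Includes scenario construction for
    excitatory/inhibitory split and applied-current ordering experiments,
    episode detection, pairwise trace divergence analysis, and bit-exact
    trace input/output.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    utils,
    yaml
LinkingTo: Rcpp
Suggests:
    jsonlite,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
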