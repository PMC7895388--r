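Package: switchmap
Title: Parameter Space Mapping for Biological Switching Systems
Version: 1.0.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Exact algebraic decomposition of parameter space for switching
    ordinary differential equation models of gene regulation, in the sharp
    (Heaviside) limit of Hill nonlinearities, followed by region-guided
    numerical exploration at finite Hill exponents. Implements the two-cell
    autoregulatory model of oocyte selection in the Drosophila germline cyst:
    enumeration of attracting switching domains, closed-form per-domain fixed
    points, symbolic attractor-membership inequalities, the catalog of
    steady-state configurations and their connected parameter-space regions,
    the region adjacency graph and its distance statistics, and sampling-based
    estimation of symmetry-breaking density for finite Hill exponents. A
    one-dimensional autocatalytic toy model is included as a fully worked
    small instance.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    deSolve,
    igraph,
    jsonlite,
    stats,
    utils
Suggests:
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
NeedsCompilation: yes
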