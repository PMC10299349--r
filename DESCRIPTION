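Package: cellcover
Title: Minimal Marker Gene Panels by Partial Set Multi-Cover
Version: 0.1.0
Authors@R:
    person("Marker", "Panels", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Selects minimal-weight marker gene panels per cell class from
    binarized single-cell expression by solving a depth-d, rate-(1-alpha)
    partial set-multi-cover integer program with an exact branch-and-bound
    solver, a greedy fallback and a brute-force oracle. Includes nested panel
    expansion, cross-dataset panel transfer via covering rates, cell-type
    mapping through normalized covering rates, panel-quality metrics
    (redundancy, intersection, balanced accuracy), a zero-inflated synthetic
    data generator with planted markers, and a command-line interface.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    methods,
    stats,
    utils,
    tools,
    Matrix,
    jsonlite,
    Rcpp
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
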