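Package: hopfec
Title: Directed Effective Connectivity from the Hopf Whole-Brain Model
Version: 0.1.0
Authors@R: person("hopfec", "maintainers", email = "hopfec@example.org",
                  role = c("aut", "cre"))
Description: Simulates networks of coupled Stuart-Landau oscillators (the
    normal form of a supercritical Hopf bifurcation), computes functional and
    time-lagged functional connectivity from band-limited signals, and
    recovers a directed effective-connectivity matrix by an error-correction
    update that matches simulated to empirical correlation structure.
    Includes a synthetic multi-subject resting-state cohort generator for
    parameter-recovery validation, ROI-level reporting utilities, delimited
    text input/output, and a command-line interface.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp,
    jsonlite,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    optparse,
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = FALSE)
RoxygenNote: 7.3.3
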