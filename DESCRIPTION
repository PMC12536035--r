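Package: phasechimera
Title: Chimera States in Kuramoto Networks and Hippocampal-Like Theta Phase Precession
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Simulates chimera states in Kuramoto oscillator networks (a nonlocally
    coupled ring and two weakly coupled populations), converts phase trajectories into
    spike rasters and phenomenological local-field-potential traces, quantifies
    synchronized and unsynchronized domains with mean phase velocity profiles and their
    ratios, and detects theta phase precession, phase locking, and theta sequences in
    spike rasters. Also trains a Dale's-law-constrained network of Izhikevich spiking
    neurons with FORCE / recursive least squares to embed a two-population chimera, so
    that single trained neurons exhibit phase precession relative to the decoded theta
    rhythm.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    Matrix,
    methods,
    tibble,
    dplyr,
    purrr,
    rlang,
    ggplot2,
    generics,
    jsonlite,
    yaml,
    stats,
    utils,
    tools
LinkingTo: Rcpp, RcppArmadillo
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
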