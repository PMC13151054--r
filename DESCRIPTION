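Package: gasport
Title: Gas Transport Pathways and Grid Markov State Models for Buried Active Sites
Version: 0.1.0
Authors@R: person("Package", "Author", email = "maintainer@example.org",
    role = c("aut", "cre"))
Description: Detects and traces dioxygen access and egress events in
    flooded-gas molecular dynamics trajectories of metalloenzymes, classifies
    pathways by residue contacts, builds grid-discretized Markov state models
    of gas positions relative to the catalytic metal, and computes
    transition-path-theory kinetics (committors, reactive flux, mean
    first-passage times). Ships a Brownian-dynamics synthetic gas simulator
    with cavity traps and closed-form/brute-force first-passage oracles so the
    whole analysis chain is testable against known kinetics.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Matrix,
    Rcpp,
    bio3d,
    data.table,
    igraph,
    methods,
    stats,
    tools,
    utils,
    yaml
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    optparse,
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
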