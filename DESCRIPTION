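Package: chromsim
Title: Stochastic Simulation of Polycomb/Trithorax Chromatin States
Version: 1.0.0
Authors@R:
    person("Package", "Maintainer", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Event-based stochastic simulator of a nucleosome array carrying
    four Polycomb/Trithorax histone modifications (H3K27me3, H3K27ac,
    H3K4/36me, H2Aub). Each half-nucleosome occupies one of 12 modification
    states; position-paired halves form 144 whole-nucleosome states classified
    into active, silent, bivalent and unmodified categories. Seven recruited
    read-write or read-erase enzyme complexes, a recruitment-independent
    conversion channel, direct deacetylation and deubiquitination channels,
    and periodic replication drive the dynamics. Includes trajectory analyses
    (category occupancy, 144-state occupancy landscapes, bistability and
    dominance classification, bivalent-mark co-occurrence statistics), one-
    and two-parameter sweeps producing phase diagrams, TSV/JSON input and
    output, and a command-line interface.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp,
    jsonlite,
    optparse,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
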