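Package: cladiw
Title: Implied-Weighting Maximum Parsimony for Morphological Character
    Matrices
Version: 1.0.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Cladistic analysis of discrete morphological character
    matrices under maximum parsimony with Goloboff implied weighting.
    Provides a validated S4 data model and readers/writers for TNT and
    NEXUS matrices (including polymorphic, missing and inapplicable
    cells), Fitch optimization of unordered multistate characters,
    heuristic tree search by random addition sequences with tree
    bisection-reconnection (TBR) branch swapping under equal weights or
    the concave fit function k/(k + extra steps), mapping of unambiguous
    character-state changes on a rooted tree with classification of each
    change as a global or local apomorphy, a simulator for character
    evolution on random topologies, and a small command-line surface.
    Ships a packaged transcription of a published 68-taxon by
    99-character matrix for the woodlouse flies (Diptera:
    Rhinophoridae) together with its character list and named clades.
License: MIT + file LICENSE
Encoding: UTF-8
Depends:
    R (>= 4.1)
Imports:
    methods,
    stats,
    utils,
    ape,
    Rcpp,
    yaml
LinkingTo:
    Rcpp
Suggests:
    testthat (>= 3.0.0),
    phangorn,
    jsonlite
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
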