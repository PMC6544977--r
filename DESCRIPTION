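Package: hsmattract
Title: Qualitative Attractor Analysis of Hybrid System Models of Gene Regulation
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Qualitative analysis of gene regulatory networks described as hybrid
    system models: continuous protein concentrations coupled to discrete,
    hysteretic binding-site states through association/dissociation thresholds
    and discrete control functions. Enumerates all threshold orderings
    compatible with partial affinity constraints, builds the characteristic
    graph of binding-site modes for each ordering, identifies stable behaviours
    (attractors) via strongly connected components filtered by progress
    indicators, classifies attractors across orderings by canonical behaviour
    signatures, and mines threshold-order conditions shared by a behaviour.
    Includes a two-gene toy network and a phage lambda lysis-lysogeny switch
    model as executable fixtures, and an exact event-driven numeric simulator
    with piecewise-linear kinetics used to validate the characteristic graph's
    over-approximation property.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    igraph,
    jsonlite,
    stats,
    utils
Suggests:
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
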