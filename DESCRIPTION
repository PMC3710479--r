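Package: rxnbool
Title: Bipartite Boolean Modelling of Reaction-Contingency Networks
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Translates reaction-contingency network definitions of
    signal-transduction systems into executable bipartite Boolean models,
    with one Boolean variable per elemental reaction and per elemental
    state and distinct update-rule semantics for each class. Supports a
    text "quick" input format and tabular reaction/contingency lists,
    synchronous simulation with perturbation schedules and point/cyclic
    attractor detection, random-order asynchronous ensemble simulation,
    complete and reachable state-space enumeration with basin analysis,
    clustered binary time-course heat maps, exports to BoolNet-style
    .bnet, GraphML and DOT, and a contrasting component-level "classical"
    Boolean export that demonstrates the loss of signal specificity.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    dplyr,
    generics,
    ggplot2,
    igraph,
    jsonlite,
    rlang,
    stats,
    tibble,
    utils,
    withr
Suggests:
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
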