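Package: liftwalk
Title: Lifted Quantum Walks for Idea Propagation and Group Decision Making
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Simulates discrete-time lifted quantum walks on small agent
    networks (line and ring graphs) in which a binary idea spreads through
    asymmetric, controlled-rotation interactions.  The network state acts as
    the controller of a block-diagonal controlled-unitary while a mirrored
    copy is the target; each step lifts the reduced state by a tensor product
    with itself, evolves it, traces out the controller, and applies a
    projective stopping measurement.  Includes gate factories for 3-agent
    line and ring graphs and a generator for n-agent rings, a walk engine
    with a cumulative stopping rule, group-decision runs with two consensus
    stopping states, and mid-walk partial-measurement experiments that
    expose quantum interference (violations of classical total probability).
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    generics,
    ggplot2,
    jsonlite,
    rlang,
    tibble,
    yaml
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
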