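Package: stablemotifs
Title: Attractor Identification and Control of Logical Intracellular Networks
Version: 0.9.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Tools for the analysis and control of logical (Boolean) models of
    intracellular networks. Finds network attractors through stable motifs --
    self-sustaining strongly connected sets of node states that act as points
    of no return in the dynamics -- and organizes them into a succession
    diagram whose leaves are the (quasi-)attractors of the model. From the
    succession diagram the package computes stable motif control sets
    (interventions that guarantee convergence to a chosen attractor from any
    initial state, even when applied transiently) and stable motif blocking
    sets (interventions that eliminate an unwanted attractor). Interventions
    can be validated by stochastic general-asynchronous simulation and in a
    continuous setting after automatic translation of the Boolean model into
    a Hill-type ordinary differential equation model. Ships transcriptions of
    the T-LGL leukemia and helper T cell differentiation case-study models.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    igraph,
    jsonlite,
    deSolve,
    Rcpp,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
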