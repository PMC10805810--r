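Package: kgsdl
Title: Knowledge-Graph Orchestrated Distributed Self-Driving Laboratories, Desk-Scale
Version: 0.1.0
Authors@R:
    person("KGSDL", "Developers", email = "kgsdl@example.org", role = c("aut", "cre"))
Description: A desk-scale re-creation of a dynamic-knowledge-graph framework for
    distributed self-driving laboratories. Scientists' goal requests trigger
    autonomous design-make-test-analyse cycles executed by software agents over
    an in-memory triple store with Turtle provenance export. The physical labs
    are replaced by a seeded plug-flow-reactor kinetic model of the
    base-catalysed aldol condensation of benzaldehyde and acetone, with a
    synthetic HPLC chromatogram generator including injectable fault modes.
    Experiment design uses Thompson-sampling efficient multi-objective
    optimisation (TSEMO): Gaussian-process surrogates, spectral posterior
    sampling, NSGA-II search and hypervolume-improvement selection, supporting
    collaborative multi-lab closed-loop cost-yield optimisation with full
    provenance and lineage queries.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    jsonlite,
    stats,
    utils
Suggests:
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
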