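Package: divdec
Title: Division-Decision Models of Spontaneous Pattern Formation
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Simulation and analysis of one-dimensional division-decision
    systems: cells carrying an identical signed-ternary Boolean gene network
    grow from a single cell by synchronous division, signal to contacting
    neighbours, and update binary gene states. The package quantifies
    positional information (mutual information between cell state and
    position) and the potential information held in the concatenated
    state/contact matrix, exhaustively screens all single- and two-gene
    networks for pattern-forming ability, enumerates fixed points and
    attractor basins at fixed cell counts, measures robustness to update
    noise and asynchronous division, provides a continuous Hill-ODE
    counterpart with AND/OR regulatory logic and a noise-resistance score,
    and re-derives the information trajectory of early C. elegans
    development from booleanized expression and cell-contact tables.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    deSolve,
    jsonlite,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
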