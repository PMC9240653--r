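Package: gemsim
Title: Simulation and Analysis for Multi-Person Adaptive Metronomes
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: An event-driven re-implementation of a multi-person adaptive
    metronome: the metronome shifts each upcoming tone by a fraction (alpha)
    of the current (group-mean) tap asynchrony. The package couples this
    engine to stochastic virtual tappers built on the Wing-Kristofferson
    two-level timing model (central timekeeper noise plus motor delays, with
    linear phase correction), runs full experiment designs with randomized
    adaptivity order, reads and writes the device's 12-byte binary event
    packets and a tidy CSV layout, computes per-trial synchrony metrics
    (individual and group SD asynchrony, individual-minus-group differences,
    within-window cross-tapper spread, tapper ranks, adaptivity benefit),
    applies missed-tap exclusion rules, and scores post-trial ratings into a
    single Enjoyment factor from fixed loadings.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    graphics,
    jsonlite,
    stats,
    utils
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
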