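Package: structdrift
Title: Structural Drift of Ordered Populations via Sequential Learning
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Simulation and analysis of structural drift: selectively neutral
    genetic drift generalized to ordered populations generated by unifilar
    probabilistic finite-state machines (epsilon-machines).  Provides a library
    of canonical processes (alternating, fair/biased/fixed coin, golden mean,
    even, periodic), closed-form information measures (allelic entropy,
    allelic complexity, population diversity) and a structural-stasis test,
    classical Fisher-Wright binomial Monte Carlo drift with Kimura-Ohta
    fixation/deletion-time theory, a sequential-learning drift engine with
    structural innovation (state cloning with likelihood selection) and
    structural loss (state merging with AICc selection), and
    isostructural-subspace analysis: topology signatures, complexity-entropy
    diagrams, and pathway decomposition of stasis times.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp,
    jsonlite,
    stats,
    utils,
    yaml
LinkingTo: Rcpp
Suggests:
    igraph,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
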