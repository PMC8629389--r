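Package: socfix
Title: Fixation Probabilities of Social-Goods Producers on Graphs
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Exact computation of fixation probabilities for producers and
    non-producers of social goods in graph-structured populations under
    death-Birth and Birth-death updating at arbitrary selection intensity.
    Supports proportional (pp), fixed-and-diffuse (ff) and
    concentrated-and-fixed (cf) goods, the exponential payoff-to-fecundity
    map, uniform and temperature mutant initialization, reduced Markov
    chains for the cycle and the star alongside a brute-force chain over
    all trait configurations of small graphs, closed-form star expressions,
    a Monte Carlo trajectory sampler, selection-condition classification and
    selection-intensity sweeps with peak detection.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Matrix,
    jsonlite,
    methods,
    optparse,
    stats,
    utils,
    yaml
Suggests: testthat (>= 3.0.0)
Config/testthat/edition: 3
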