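Package: ateca
Title: Asynchronously Tuned Elementary Cellular Automata
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Simulation of elementary cellular automata (ECA) under three
    update regimes: classical synchronous updating, probabilistically
    asynchronous updating, and asynchronously tuned updating (AT-ECA), in
    which a random per-step update order splits cells into active and
    passive roles and a per-cell active rule is perpetually re-tuned
    against a fixed passive rule. Provides quantitative measures of
    computational universality (reachable-state cardinality) and
    computational efficiency (mean first-hitting time with penalty), the
    per-interval minimum-efficiency step function expressing the
    universality-efficiency tradeoff, tradeoff-break statistics comparing
    update regimes, and descriptive criticality diagnostics (density-decay
    power-law exponent, periodogram spectral slope).
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp,
    jsonlite,
    stats,
    tools,
    utils,
    graphics,
    grDevices,
    yaml
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr,
    png,
    optparse
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
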