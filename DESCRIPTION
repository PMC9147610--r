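Package: poretime
Title: Polymer Translocation Times Through Nanopores
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Models the time a polymer (e.g. single-stranded DNA or RNA)
    takes to translocate through a nanopore in a membrane. Provides the
    entropic free-energy landscape over the translocation coordinate, the
    mean-first-passage-time double integral with its closed-form scaling
    limits, a Crank-Nicolson/fully-implicit drift-diffusion solver for the
    escape probability and first-passage-time distribution, an
    Euler-Maruyama stochastic escape-event simulator with histogram mode
    analysis, and a configuration/run layer for reproducible sweeps. All
    routes are cross-validated against analytic limits (pi^2 N^2/16
    diffusive constant, N^2/2 flat landscape, inverse-Gaussian drift
    first-passage law).
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    graphics,
    grDevices,
    jsonlite,
    stats,
    utils,
    withr,
    yaml
Suggests:
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
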