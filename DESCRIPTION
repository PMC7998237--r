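Package: gametegame
Title: Game-Theoretic Models of Gamete Size Evolution and the Origin of Anisogamy
Version: 1.0.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for analysing gamete-competition games for the evolution of
    anisogamy (gamete size dimorphism, the origin of the female and male sexes).
    Provides exact and approximate closed-form equilibria of the two-mating-type
    gamete size game, a generalized (inefficient) gamete size-number trade-off,
    threshold gamete survival with power-law zygote survival, convergence-stability
    and invasibility analysis, bisection-based detection of the isogamy-anisogamy
    threshold, adaptive-dynamics trajectory integration, and a Fisher-consistent
    gamete-limitation extension with pluggable fertilization models. Includes a
    command-line interface for reproducible parameter scans and reports.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    graphics,
    grDevices,
    jsonlite,
    stats,
    utils
Suggests:
    knitr,
    optparse,
    rmarkdown,
    testthat (>= 3.0.0)
VignetteBuilder: knitr
Config/testthat/edition: 3
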