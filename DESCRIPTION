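Package: potatogap
Title: Potential Yield Simulation and Yield-Gap Analysis for Potato
Version: 1.0.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: A radiation-driven (LINTUL-type) daily growth simulator for
    potato built on beta-function canopy dynamics and Gompertz tuber
    partitioning over thermal time, together with the estimation
    procedures that parameterize it from field observations (nonlinear
    least-squares canopy and harvest-index fits, radiation-use-efficiency
    regression, quadratic early-cover interpolation), seasonal yield-gap
    decomposition against actual farm yields, late-blight epidemic
    analysis (AUDPC, disease-yield regression, logistic tuberization
    curves), and a seeded synthetic-data generator that emulates the
    field trials so every stage is testable end to end.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    minpack.lm,
    jsonlite,
    stats,
    utils,
    graphics
Suggests:
    testthat (>= 3.0.0),
    pracma
Config/testthat/edition: 3
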