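Package: alpbpk
Title: Whole-Body PBPK Modelling and Toxicity-Based Dose Finding for
    Atractylodin (Atractylodes lancea)
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Perfusion-limited whole-body physiologically based
    pharmacokinetic (PBPK) simulation of orally dosed atractylodin, the
    marker active constituent (14%) of Atractylodes lancea (AL) rhizome
    extract, with non-compartmental analysis, absolute average fold error
    (AAFE) and visual predictive check model qualification, normalized
    sensitivity coefficients, an Emax-based hematological toxicity risk
    model anchored to an observed baseline risk, a liver unbound-Cmax
    hepatotoxicity surrogate, seeded Monte-Carlo virtual populations, and
    decision rules selecting first-in-human, maximum-tolerated-dose and
    phase-2A regimens from an enumerated once/twice/four-times-daily
    regimen grid. Includes seeded generators for synthetic plasma
    concentration-time profiles and longitudinal immune panels, plus
    paired statistical comparison utilities for immune-panel data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    deSolve,
    jsonlite,
    stats,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
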