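Package: outflowr
Title: Aqueous Humor Dynamics from Ocular Perfusion Experiments
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Analysis pipeline for multi-step ocular perfusion experiments in
    mice. Simulates pressure-step perfusions of enucleated eyes, detects
    steady-state plateaus with Savitzky-Golay filtering and slope criteria,
    estimates reference outflow facility and the pressure-nonlinearity factor
    beta by power-law regression with 95% confidence intervals, recovers
    reference ocular compliance from step responses, adjusts estimates for eye
    size, and performs cohort-level statistics: robust outlier rejection in the
    log domain, interocular correlation, bilateral averaging with quadrature
    confidence intervals, and age regressions with Bonferroni correction.
    Also quantifies pressure responses of Schlemm's canal luminal area and the
    iridocorneal angle from segmented imaging tables.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    deSolve,
    minpack.lm,
    signal,
    stats,
    utils,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
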