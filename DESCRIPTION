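Package: elasmodem
Title: Stochastic Demographic Analysis of Exploited Elasmobranch Populations
Version: 0.1.0
Authors@R: person("DAQUA", "Maintainers", email = "maintainer@example.org",
    role = c("aut", "cre"))
Description: Life-table and Leslie-matrix demography for data-poor shark
    stocks assessed from life-history parameters and fishery catch
    compositions. Provides the classical empirical natural-mortality
    estimators (Pauly, Hoenig, Jensen, Rikhter-Efanov, Mollet-Cailliet,
    Hewitt-Hoenig, Peterson-Wroblewski and the two-phase Chen-Watanabe),
    catch-curve and Beverton-Holt total-mortality estimation from length or
    age compositions, age-structured projection matrices under fishing
    scenarios with eigen-analysis and elasticity decomposition, Monte Carlo
    propagation of parameter uncertainty, exponential decline projection
    against IUCN criterion E, intrinsic rebound potential and the extinction
    fishing mortality, and a synthetic gillnet catch generator with known
    truth for estimator validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse
Config/testthat/edition: 3
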