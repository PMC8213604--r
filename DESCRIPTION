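Package: bioclimdyn
Title: Slow-Fast Decomposition, Dynamical Reconstruction and UTCI
    Modelling of Monthly Climate Series
Version: 0.1.0
Authors@R:
    person("bioclimdyn", "maintainers", email = "maintainers@example.org",
           role = c("aut", "cre"))
Description: Tools for analysing long monthly records of sunshine duration,
    precipitation and air temperature as a coupled climate system.  A series
    is split into a multidecadal slow trend (moving average plus zero-phase
    Butterworth low-pass), a 12-month seasonal profile and a standardized
    correlated residual; the residual is modelled as a low-order
    autoregressive process; the three slow trends are reconstructed as a
    three-dimensional autonomous cubic-polynomial ODE system by phase-space
    trajectory fitting; the fitted system is analysed for equilibria, their
    linear stability and the limit-cycle period; and the Universal Thermal
    Climate Index (UTCI) is computed from the meteorological variables under
    constant wind-speed scenarios via a mean-radiant-temperature radiation
    budget.  A synthetic-data generator with a known benchmark dynamical
    system makes every stage testable without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
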