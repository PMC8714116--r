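Package: kerataggr
Title: Steady-State Kinetics of Keratin Aggregation in Cells Co-Expressing
    Wild-Type and Mutant Keratin
Version: 1.0.0
Authors@R:
    person("Package", "Author", email = "author@example.com",
           role = c("aut", "cre"))
Description: Mass-action reaction-network model of keratin turnover in
    keratinocytes that co-express wild-type and mutant keratin 14.  Eight
    coupled ordinary differential equations track both keratin species
    across soluble, particulate, filamentous and aggregate phases, with
    aggregates formed by asymmetric (gamma:1) binding of wild-type and
    mutant particles.  The package finds the dynamical equilibrium by
    stiff adaptive integration (LSODA) and, independently, by an algebraic
    reduction of the stationarity conditions; sweeps the mutant keratin
    fraction to locate the peak aggregate-to-filament ratio; maps that
    peak over the (gamma, lambda_agg) parameter plane; generates seeded
    synthetic noisy observations of the aggregate burden; and recovers the
    two free aggregation parameters from such data by least squares on the
    log scale.
License: MIT
Encoding: UTF-8
Imports:
    deSolve,
    graphics,
    jsonlite,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
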