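Package: fermkin
Title: Batch Fermentation Kinetics: Logistic Growth, Maintenance, and
    Luedeking-Piret Product Formation
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Models batch shake-flask fermentation of an oleaginous
    DHA-producing microorganism with a three-state ODE system: logistic
    biomass growth toward a carrying capacity, glucose consumption with a
    Pirt maintenance term, and Luedeking-Piret (mixed growth-associated)
    product formation. Provides forward simulation onto arbitrary sampling
    grids, a synthetic shake-flask data generator with replicate
    measurement noise, joint bounded least-squares parameter estimation
    with multistart, a per-variable goodness-of-fit statistic, and the
    endpoint kinetic descriptor panel (volumetric rates, specific growth
    rate, observed yields) over the window from inoculation to peak
    product titer.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    deSolve,
    minpack.lm,
    lhs,
    jsonlite,
    yaml,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
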