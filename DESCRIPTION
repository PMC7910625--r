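Package: edemaload
Title: Lifetime Corneal Edema Load Modelling for Contact Lens Wear
Version: 1.0.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Models corneal swelling and deswelling over the 24-hour
    sleep/wake cycle as a function of contact lens oxygen transmissibility
    (Dk/t), assembles piecewise swelling trajectories for compliant and
    noncompliant daily-wear and extended-wear schedules, and integrates
    them into cumulative "edema load" exposures over years to decades of
    wear. Includes a between-subject random-effect model for high
    corneal swellers (highest of k wearers), weighted nonlinear
    least-squares estimation of all model coefficients from collated
    swelling data, and a synthetic literature-corpus generator for
    parameter-recovery studies. A small command-line driver exposes the
    simulator, the load tables, the fitter and the generator.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    graphics,
    minpack.lm,
    lme4,
    jsonlite,
    optparse
Suggests:
    withr,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
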