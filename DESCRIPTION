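Package: osteosim
Title: Mechanostat-Driven Bone Remodeling Through Menopause and Ageing
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Simulates femur-averaged bone mineral density through the
    menopausal transition with a daily-stepped basic multicellular unit
    (BMU) remodeling model: layered tissue composition with secondary
    mineralization, delayed formation and resorption windows, a
    mechanostat stimulus with slow accommodation, and multiplicative
    kappa(t) modifiers encoding the permanent menopausal shift plus a
    long-term ageing drift in BMU activation frequency and focal bone
    balance. Provides least-squares calibration of the kappa parameters
    to relative BMD observation series, a seeded synthetic-observation
    generator, overload/underload scenario analysis, and WHO-style
    osteoporosis threshold computations on reference population
    statistics.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Rcpp,
    jsonlite,
    stats,
    graphics,
    grDevices,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
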