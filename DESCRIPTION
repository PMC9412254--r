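Package: thermoniche
Title: Population-Based Threshold Modelling of the Seed Germination Thermal Niche
Version: 0.1.0
Authors@R:
    person("Package", "Maintainer", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Tools to quantify the temperature niche for seed germination of
    dormant seed lots with a population-based threshold (PBT) model. Germinable
    fractions are described by normally distributed lower- and higher-limit
    temperatures (Tl50, Th50), germination timing by sub- and supra-optimal
    thermal time, and dormancy release in dry storage by a thermal
    after-ripening time model and the rate of widening of the thermal niche
    (RWTN, hours of storage per degree Celsius increase in Th50). Includes
    multi-temperature nonlinear least-squares fitting of stage parameters, a
    synchrony-of-germination statistic (SOG), classification of nondeep
    physiological dormancy types, prediction of field germination timing from
    monthly climate normals, a seeded synthetic-data generator emulating a
    multi-population germination trial, and a command-line pipeline.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    grDevices,
    graphics
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    withr
Config/testthat/edition: 3
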