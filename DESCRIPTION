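Package: bmpkit
Title: Biochemical Methane Potential Assay Analysis and Kinetics
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Analysis chain for biochemical methane potential (BMP) batch
    assays of lignocellulosic substrates. Converts raw gas-flow-meter logs to
    blank-corrected specific methane yield curves at standard temperature and
    pressure, fits the Modified Gompertz, Logistic, Cone and first-order
    kinetic models of cumulative methane production, estimates first-order
    substrate hydrolysis rate constants, computes the theoretical methane
    potential and biodegradability from elemental composition via the Buswell
    total-reaction stoichiometry, classifies FT-ICR-MS dissolved organic
    matter formulas into Van Krevelen compound classes, and evaluates
    methane-to-electricity economics. Includes a seeded synthetic-data
    generator emulating an automatic methane potential test system so the
    whole pipeline is testable without instrument data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    minpack.lm,
    stats,
    utils
Suggests:
    jsonlite,
    optparse,
    testthat (>= 3.0.0),
    withr,
    yaml
Config/testthat/edition: 3
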