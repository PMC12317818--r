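Package: nutriDEB
Title: Nutritional Dynamic Energy Budget Model for Farmed Fish
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Simulates growth, oxygen consumption, carbon dioxide, total
    ammonia nitrogen (TAN) and faecal waste of farmed fish with a Dynamic
    Energy Budget (DEB) abj model extended by a two-substrate
    (protein/non-protein) synthesising-unit digestion module and meal-driven
    stomach dynamics. Feeds are described by proximate composition and
    apparent digestibility; meals are discrete events refilling a
    capacity-limited stomach; mineral fluxes follow from full C/H/O/N
    elemental balance. Includes diet response surfaces (protein-to-energy
    effects on intake and assimilation), gastric-evacuation curves,
    calibration of the digestion parameters by least squares, and a
    synthetic-data generator for testing.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    deSolve,
    minpack.lm,
    stats,
    utils,
    yaml,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    optparse,
    withr
Config/testthat/edition: 3
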