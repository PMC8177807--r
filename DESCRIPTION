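Package: goosefuel
Title: Time Budgets, Energy Budgets and Premigratory Fueling in Wintering Geese
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Tools to turn GPS/accelerometer tracking of wintering geese into
    behavioral time budgets and simulated body-mass trajectories. Includes a
    random-forest behavior classifier on triaxial accelerometer burst features
    (ODBA, pitch, axis derivatives), NOAA-style solar and low-precision lunar
    ephemeris for day length and moonlit night hours, a bioenergetics model of
    existence and thermoregulation costs, a growing-degree-day model of
    metabolizable intake rate, a body-mass trajectory recursion with
    counterfactual foraging scenarios, segmented-regression estimation of the
    fueling onset, and a parameter sensitivity analysis. A seeded synthetic-data
    generator emulates the tracking, weather and field-intake inputs so the
    whole pipeline is testable end to end.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    tools,
    randomForest,
    geosphere,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
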