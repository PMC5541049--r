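Package: climsens
Title: Climate Sensitivity Risk Assessment for High-Impact Pathogens
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Semi-quantitative risk assessment of the climate sensitivity of
    high-impact human and domestic-animal pathogens. Aggregates signed
    literature-evidence scores into per-pathogen, per-climate-driver median
    scores and sensitivity profiles; summarises driver counts, frequencies and
    co-occurrence overall and by taxon or transmission route; tests which
    pathogen characteristics (zoonotic status, emergence, transmission route,
    geographic spread, H-index) associate with climate sensitivity using 2x2
    contingency statistics and logistic regression; and attributes human
    disease burden (Global Burden of Disease DALYs) to climate-sensitive
    diseases. Includes a seeded synthetic-data generator emulating the
    structure of such evidence datasets so every stage is testable and effect
    sizes are recoverable.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    graphics,
    jsonlite,
    yaml
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
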