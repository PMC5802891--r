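Package: bbwohab
Title: Boreal Forest Landscape Simulation and Black-Backed Woodpecker
    Habitat Productivity
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A desk-scale, cohort-based boreal forest landscape simulator
    (succession, seed dispersal, stochastic fire, spruce budworm outbreaks,
    harvesting, climate-period parameter switching) coupled to a rule-based
    habitat classifier and potential-productivity model for the Black-backed
    Woodpecker (Picoides arcticus), plus the factorial sensitivity analysis
    (omega-squared effect sizes, percentage productivity and biomass
    differences) used to rank harvesting, fire-regime change and stand-scale
    climate effects as drivers of habitat change. Includes a synthetic
    landscape generator emulating a latitudinal conifer-deciduous gradient
    and a negative-exponential stand-age structure.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    data.table,
    EBImage,
    jsonlite,
    stats,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
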