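Package: heatwalk
Title: Dynamic Heat-Stress Accumulation and Walkable-Route Assessment for
    Fifteen-Minute Cities
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Models pedestrian heat exposure as a cumulative dose: UTCI
    (Universal Thermal Climate Index) values are banded into heat-stress
    levels 0-4, stress accumulates along a walk as level times duration, and
    walkability is the remaining tolerant heat discomfort R_t = H - S_t
    against a calibrated budget H. Provides budget-constrained best-route
    search on street networks (Pareto label-setting over stress and
    distance), per-edge walkability maps from neighborhood entrances,
    population-weighted aggregation across neighborhoods with public-service
    siting classes, calibration of H from ordinal walking-survey panels
    (discomfort-onset timelines, Cronbach's alpha), and synthetic generators
    for street networks, spatially correlated UTCI fields, and survey panels.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    jsonlite,
    stats,
    utils,
    graphics,
    grDevices
Suggests:
    igraph,
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
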