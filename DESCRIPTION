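Package: featherbeam
Title: Cantilever-Beam Mechanics of Feather Barbs and Barbules
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Mechanical models of the hierarchical micro-structure of bird
    flight feathers. Treats each barbule (and each barb) as a cantilevered
    beam and provides modal analysis of the clamped-free Euler-Bernoulli
    beam (transcendental characteristic-equation roots, natural
    frequencies, mode shapes, excitation amplitude), the first-mode
    space-time vibration response with tip kinematics including the
    droplet-shedding speed, static deflection of linearly tapered
    barbules and barbs under a distributed air load and under a point
    combing load, and a seeded synthetic generator of rachis-barb-barbule
    feather geometries so the whole pipeline can be exercised without
    microscopy data. Includes reproducible pipeline runners that emit CSV
    and JSON reports.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    jsonlite,
    rlang,
    stats,
    utils,
    yaml
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
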