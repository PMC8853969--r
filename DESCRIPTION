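Package: flywaysim
Title: Energetics-Based Daily Simulator of Non-Breeding Waterfowl Migration
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: A population-level, daily-time-step simulator of waterfowl
    movement and energetics during the non-breeding season (September to
    May). The landscape is a grid of stopover nodes carrying forage and
    roosting habitat; daily weather drives a snow/freeze weather severity
    index that masks available habitat. The population is structured into
    body-condition (fat) classes with condition-dependent survival; birds
    gain fat by rationed foraging, depart under Monod-type pressure from
    weather severity, body condition, breeding-ground distance and daily
    gain, and select arrival nodes through a Cobb-Douglas attractiveness
    function with seasonally varying weights. Flight speed, cost and range
    follow Pennycuick aerodynamic theory. Includes seeded synthetic
    landscape and weather generators, migration-path metrics
    (center-of-mass track, top-occupancy nodes), and a command-line
    interface.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    data.table,
    geosphere,
    jsonlite,
    stats,
    utils,
    yaml
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
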