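Package: mvpasim
Title: Agent-Based Simulation of Children's Physical Activity in Urban Environments
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Discrete-time (1-minute step) agent-based model of 9-11-year-old
    children's weekday activity schedules and accumulation of moderate-to-vigorous
    physical activity (MVPA) in an urban environment. Includes a synthetic-city
    generator and a GeoJSON loader for the spatial setting (data zones with
    deprivation quintiles, land-use sites, homes, schools, shops, a walkable road
    network), a heterogeneous agent population with a within-school friendship
    network and formal sport activities, behavioural equations for after-school
    play, neighbourhood play with presence feedback, friend meetings and shopping,
    rank-based sequential-roulette site selection, walk-versus-car travel-mode
    choice, per-minute MVPA accumulation with peer adjustment, eight intervention
    scenarios, frequency calibration against time-use targets, and sensitivity
    sweeps over the peer-influence parameters.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    igraph,
    jsonlite,
    stats,
    utils,
    graphics
Suggests: testthat (>= 3.0.0), yaml
Config/testthat/edition: 3
RoxygenNote: 7.3.3
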