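Package: accelwalk
Title: Randomly Accelerated Walker Models of Human Mobility
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Tools for modelling vehicular human mobility as a randomly
    accelerated walk on a hierarchy of transport layers. Provides the
    analytic speed and displacement distributions of the Poisson kick
    model and of a Brownian-velocity null model, stochastic trip
    simulators, the estimation pipeline that recovers the model
    parameters from binned trip tables (base speed, kick rate, speed
    gap, mean travel time), heavy-tail model comparison for displacement
    distributions (truncated power law, stretched exponential,
    exponential), GPS engine-event trip extraction with micro-stop and
    signal-loss handling, free-flow speed estimation, and a
    ground-truthed synthetic GPS fleet generator for end-to-end testing.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    tools,
    pracma,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
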