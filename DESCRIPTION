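Package: streetcover
Title: Street-Level Imagery Availability, Age, and Age-Variance Audits for Cities
Version: 0.1.0
Authors@R:
    person("Urban Imagery", "Tools", email = "tools@example.org", role = c("aut", "cre"))
Description: Quantifies the availability, age, and age variance of
    street-level panoramic imagery across cities and relates them to
    subcity socioeconomic conditions. Places a 500-m point lattice over
    projected city boundaries, computes road length within 100-m buffers
    to filter eligible points, audits points against an imagery-metadata
    provider (a deterministic synthetic provider is bundled), aggregates
    availability and image age to subcity, city, and country levels,
    builds combined socioeconomic Z-score indices, and fits mixed-effect
    logistic and linear regression models with city-level random
    intercepts and spatial random slopes. A synthetic-city generator with
    known ground truth supports end-to-end testing and parameter-recovery
    studies at desk scale.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    jsonlite,
    lme4,
    stats,
    tools,
    utils
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
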