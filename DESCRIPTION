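Package: wolfmove
Title: Movement Patterns and Resting-Site Selection of GPS-Collared Wolves
Version: 0.9.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Analysis pipeline for the movement ecology of GPS-collared
    floating wolves in human-dominated landscapes: regularisation of GPS
    trajectories, Brownian bridge movement model (BBMM) utilisation
    distributions with isopleth settlement areas, rule-based segmentation of
    trajectories into five movement patterns (post-release, settlement,
    exploration, pre-dispersal, dispersal), permutation Mann-Whitney
    comparisons of diurnal and nocturnal step lengths, spatio-temporal
    detection of resting sites with diurnality levels, and matched
    case-control (1:25) resting-site selection analysis via conditional
    logistic regression with AIC dredging and full model averaging. Includes
    a synthetic-data module that generates landscapes and behaviour-switching
    trajectories with known ground truth, so that every stage of the pipeline
    can be validated against planted truth without field data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    jsonlite,
    stats,
    tools,
    utils,
    yaml
Suggests:
    geosphere,
    optparse,
    survival,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
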