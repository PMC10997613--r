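Package: mitescan
Title: Quantification of Spider Mite Symptoms from Two-Sided Leaf Scans
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: An analytical pipeline for assessing plant susceptibility to the
    two-spotted spider mite (Tetranychus urticae) from high-resolution scans
    of detached, taped-down rosette leaves imaged from both sides. The
    package segments and orders individual leaves on a plate, pairs abaxial
    with adaxial views, detects mite eggs and black fecal pellets as discrete
    objects with confidence scores, segments chlorotic feeding damage per
    pixel, merges damage across leaf sides without double counting, and
    aggregates results into per-leaf and per-plant symptom tables in physical
    units. A susceptibility statistics layer provides reference-normalised
    relative values, one-way ANOVA with Tukey HSD compact letter displays,
    dynamic ranges, consecutive-leaf symptom distributions and leaf-side
    distributions. A seeded synthetic plate-scan generator with exact ground
    truth makes every stage testable without microscope data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    EBImage,
    tiff,
    jsonlite,
    yaml,
    tibble,
    dplyr,
    tidyr,
    readr,
    rlang,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    multcomp,
    optparse,
    ggplot2,
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
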