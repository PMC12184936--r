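Package: routexpose
Title: Route-Based Noise Exposure and Travel Mode Choice Modelling
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools to study how noise pollution and the built environment
    relate to commuting mode choice along routed itineraries. Provides a
    synthetic city generator with a known multinomial mode-choice model,
    equal-area hexagonal tessellation with conservative spatial aggregation
    of buildings, streets, points of interest and ordinal noise classes,
    shortest-path routing on mode-aware street networks, per-trip exposure
    accounting (noise-class distance shares and built-environment means),
    a rebalanced and tuned random-forest mode classifier, and model
    interpretation via Gini importance and multiclass partial dependence
    on the log-of-votes scale.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    jsonlite,
    randomForest,
    stats,
    utils,
    graphics,
    grDevices
Suggests:
    testthat (>= 3.0.0),
    arrow,
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
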