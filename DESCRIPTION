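Package: rseikit
Title: Remote Sensing Ecological Index Toolkit for Arid-Region Monitoring
Version: 0.1.0
Authors@R: person("Package", "Author", email = "maintainer@example.org",
    role = c("aut", "cre"))
Description: Computes a composite remote-sensing ecological index (RSEI) for
    arid and semi-arid landscapes from surface-reflectance band stacks: five
    component indicators (soil-adjusted vegetation index, surface water
    content index, bareness/built-up index, land surface temperature, and a
    comprehensive salinity index) are water-masked, normalized, and fused by
    principal-component analysis into a single [0,1] ecological-quality
    index. Multi-epoch tools grade index change, tabulate class transitions,
    map temporal variability (coefficient of variation) and persistence
    (rescaled-range Hurst exponent), and attribute spatial pattern to driver
    variables with an optimal-parameter geographical detector (q-statistic
    with optimal discretization). A seeded synthetic-scene simulator provides
    ground-truthed band stacks and driver rasters for desk-scale validation.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    methods,
    stats,
    utils,
    tools,
    Rcpp,
    yaml,
    jsonlite
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
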