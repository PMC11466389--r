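Package: sewershedpop
Title: Sewershed Population Profiles and Equity Comparisons for
    Wastewater-Based Epidemiology
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Characterizes the populations living inside wastewater
    monitoring catchments (sewersheds) and compares them with county and
    state populations. Delineates sewered and unsewered areas by polygon
    union and erase, selects intersecting census blocks and tracts,
    aggregates counts, American Community Survey style percentage
    estimates with margins of error, median household income, and social
    vulnerability percentile ranks into per-region population profiles,
    and flags meaningful (greater than 5 percentage point or 5 percent)
    and statistically significant differences using margin-of-error based
    Z statistics. Includes a fully synthetic nested census-geography
    generator (blocks, tracts, counties, sewersheds) with configurable
    demographic gradients and exported ground truth, so the whole
    pipeline is testable without restricted data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    dplyr,
    jsonlite,
    readr,
    stats,
    tibble,
    tools,
    utils,
    yaml
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
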