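Package: microbuffer
Title: Forest Microclimate Temperature Buffering and Its Effects on
    Understory Processes
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Predicts below-canopy (microclimate) temperature offsets from
    canopy structure and terrain using empirically fitted linear
    mixed-effects coefficients, aggregates them over stockable forest
    cells, and couples the resulting daily microclimate series to three
    temperature-sensitive understory processes: first-order decay of
    deadwood, litter and soil carbon; degree-day development and
    overwintering of the European spruce bark beetle (Ips typographus);
    and threshold-based tree establishment filters (minimum winter
    temperature, chilling, growing degree days, late frost). A paired
    simulation experiment runs macroclimate- and microclimate-driven
    landscapes on identical climate-year and wind sequences and reports
    indicators at local, meso and landscape scales. Synthetic terrain,
    weather and stand generators make every stage testable without
    external data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    optparse,
    knitr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
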