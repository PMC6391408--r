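Package: rivertn
Title: Projecting Riverine Total Nitrogen Loading Under Socioeconomic and
    Climate Scenarios
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for projecting riverine total nitrogen (TN) export for
    networks of watersheds under combined land-use/land-management (SSP) and
    precipitation (RCP) scenarios. Implements an empirical log-linear TN
    loading model driven by net anthropogenic nitrogen inputs (NANI), annual
    precipitation, extreme springtime precipitation and developed/cropland
    cover; a five-component NANI accounting scheme with census interpolation,
    fertilizer and deposition rescaling and a food/feed-import regression;
    reduction of daily precipitation to annual and extreme-percentile
    features; a scenario engine with factorial driver decomposition; and
    multi-model ensemble robustness classification (t-test plus sign
    agreement). A seeded synthetic-world generator makes every stage testable
    without external data archives.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    dplyr,
    jsonlite,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
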