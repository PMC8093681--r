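Package: radlabel
Title: Labeled Rank Abundance Diagrams Under a Competition-Fecundity Trade-Off
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for the patch-occupancy colonization model of community
    assembly under a competition-fecundity trade-off: exact forward-recursive
    equilibria, ODE integration to steady state, the continuous-competitiveness
    analytic abundance density, labeled rank abundance diagrams (RADs) with
    peak/non-peak annotation, species abundance distribution histograms,
    Simpson diversity and deviation indices, and a randomization test of
    within-group rank-distance standard deviation and mean rank position for
    grouped community abundance tables, with exact small-community enumeration,
    synthetic community generators, and config-driven pipelines.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    deSolve,
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    withr,
    yaml
Suggests:
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
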