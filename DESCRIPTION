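Package: lignoprep
Title: Multi-Criteria Efficacy Assessment of Lignocellulosic Pretreatments
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for screening and ranking single-step lignocellulosic
    pretreatments during early biorefinery design. Implements fraction
    removal and accessibility indices, the Overend-Chornet severity factor,
    composition- and removal-based screening rules, downstream
    techno-economic operating-cost roll-ups, social life-cycle indicators
    normalized by national denominators, 0-10 indicator rating
    normalization, weighted-sum efficacy scoring with configurable weight
    vectors, deterministic ranking, and Monte-Carlo weight-perturbation
    sensitivity analysis. Ships transcriptions of the study's pretreatment,
    utility, cost, and rating tables as verification fixtures, together
    with a calibrated synthetic scheme generator so the full pipeline is
    testable without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    tibble,
    jsonlite,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr,
    yaml
Config/testthat/edition: 3
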