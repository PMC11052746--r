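Package: emstwin
Title: Digital Twin, Fairness Indicators and Multi-Objective Location
    Optimization for Regional Emergency Medical Services
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for strategic and tactical analysis of regional Emergency
    Medical Services (EMS). Provides a discrete-event simulator of ambulance
    dispatch from call receipt to station return (with and without preemption
    of non-urgent services), a suite of fairness and efficiency indicators
    (Gini-based fair coverage, population and surface coverage with a
    discounted Basic Life Support contribution, second-ambulance distance,
    response-time statistics), a Pareto late-acceptance hill-climbing
    optimizer for ambulance station assignment, and a synthetic-scenario
    generator emulating a large heterogeneous region with city, rural,
    mountain and seaside areas.
License: MIT + file LICENSE
Encoding: UTF-8
Depends:
    R (>= 4.1)
Imports:
    dplyr,
    generics,
    geosphere,
    ggplot2,
    jsonlite,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    yaml
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
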