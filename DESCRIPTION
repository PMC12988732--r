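Package: eggrisk
Title: Dietary Heavy-Metal Exposure and Health Risk Assessment for Eggs
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Deterministic and probabilistic human health risk assessment of
    heavy metals ingested via egg consumption. Computes estimated daily intake
    (EDI), target hazard quotients (THQ), the hazard index (HI), carcinogenic
    risk (CR) from slope factors and total carcinogenic risk (TCR) per sampling
    area and population group; propagates input uncertainty through the risk
    equations with a seeded Monte Carlo engine and reports 95th-percentile
    decision summaries; screens concentrations against regulatory maximum
    levels; compares areas and production systems with one-way ANOVA and Tukey
    HSD; and generates synthetic multi-area concentration datasets emulating a
    nine-area, ten-eggs-per-area, ten-metal survey design for fully
    reproducible testing.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    car,
    dplyr,
    jsonlite,
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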