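Package: ttcprior
Title: Exposure-Driven Prioritization of Chemicals in Food via the
    Threshold of Toxicological Concern
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: An exposure-led workflow for prioritizing chemicals measured
    in food. Estimates chronic dietary exposure from individual
    consumption diaries and concentration monitoring data with the
    observed-individual-mean model under lower- and upper-bound
    treatment of non-detects; assigns each substance a threshold of
    toxicological concern (TTC) through a four-step decision tree
    (exclusion rules, a two-of-three cross-model genotoxicity consensus,
    organophosphate/carbamate substructure filters, Cramer classes);
    ranks substances by hazard quotient; and normalizes heterogeneous
    high-throughput screening readouts to comparable 0-100 potency
    scores. Includes a seeded synthetic-data generator emulating the
    structure of European food-monitoring and consumption-survey inputs
    so the full pipeline is testable without restricted databases.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    ChemmineOB,
    dplyr,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    yaml
Suggests:
    ChemmineR,
    jsonlite,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
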