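#!/usr/bin/env Rscript
# Stage 1: generate the synthetic study inputs.
#
# Stands in for the monitoring database (SSD1-coded concentrations), the
# two-day national consumption survey, the food translation table, the
# substance annotations and the HTS result sets. The survey size matches the
# real design the generator emulates (3,819 subjects, two recall days); every
# substance carries a planted decision-tree branch and exposure tier recorded
# in truth_table.csv.

library(ttcprior)

SEED <- 2022
params <- scenario_params(seed = SEED)  # defaults: 3,819 subjects x 2 days

message("generating synthetic scenario (seed ", SEED, ") ...")
scenario <- generate_scenario(params)
paths <- write_scenario(scenario, "results/data")

n_censored <- sum(scenario$concentrations$result_type != "VAL")
message(sprintf(
  "wrote %d tables under results/data: %d substances, %d subjects, %d concentration samples (%.0f%% censored)",
  length(paths), nrow(scenario$truth_table),
  length(unique(scenario$consumption$subject_id)),
  nrow(scenario$concentrations),
  100 * n_censored / nrow(scenario$concentrations)
))
print(table(scenario$truth_table$branch, scenario$truth_table$tier))
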