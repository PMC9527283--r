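#!/usr/bin/env Rscript
# Stage 3: the four-step TTC decision tree.
#
# Exclusion rules, two-of-three genotoxicity consensus, the
# organophosphate/carbamate substructure filter, Cramer classes. Run in both
# matching modes: the literal mode applies the patterns exactly as written;
# the relaxed mode also admits thiophosphates (P=S) and N-H carbamates.

library(ttcprior)
suppressMessages(library(dplyr))

annotations <- read_annotations("results/data/annotations.csv")

assignments <- assign_ttc(annotations, mode = "literal")
relaxed <- assign_ttc(annotations, mode = "relaxed")
write_table(assignments, "results/ttc_assignments.csv")

message("TTC outcomes (literal mode):")
print(count(assignments, outcome, ttc_value))

changed <- !mapply(identical, assignments$ttc_value, relaxed$ttc_value)
diff_codes <- assignments$substance_code[changed]
if (length(diff_codes) > 0) {
  message("substances whose threshold changes in relaxed mode: ",
          paste(diff_codes, collapse = ", "))
} else {
  message("literal and relaxed modes agree on every substance in this scenario")
}
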