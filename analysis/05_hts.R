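#!/usr/bin/env Rscript
# Stage 5: cross-assay HTS potency normalization.
#
# Heterogeneous readouts (composite scores, percent-of-maximum, AC50, rank,
# LEL) are mapped to a common 0-100 potency scale, most potent per dataset
# = 100, with a log transform for concentration readouts. The final matrix
# has one row per screened substance and one column per prediction model,
# grouped by toxicological domain.

library(ttcprior)
suppressMessages(library(dplyr))

hts_raw <- read_hts_table("results/data/hts_results.csv")
domain_map <- readr::read_csv("results/data/domain_map.csv", show_col_types = FALSE)
selection <- readr::read_csv("results/reports/screening_selection.csv",
                             show_col_types = FALSE)

scores <- normalize_hts(hts_raw)
write_table(scores, "results/hts_scores.csv")
mat <- assemble_matrix(scores, selection, domain_map)
write_table(mat, "results/reports/hts_matrix.csv")

message("normalized ", sum(scores$status == "active"), " active results across ",
        n_distinct(scores$model_id), " models; per-model max score:")
print(summarise(group_by(filter(scores, status == "active"), model_id),
                max_score = max(normalized), n_active = dplyr::n()))
message("screening matrix (", nrow(mat), " substances x ",
        ncol(mat) - 2, " models):")
print(mat)
no_data <- mat$substance_code[mat$no_hts_data]
if (length(no_data) > 0) {
  message("no HTS data available for: ", paste(no_data, collapse = ", "))
}
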