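# Seeded generators for the five input tables with known ground truth.
#
# The generator emulates the statistical structure of a European food
# monitoring database joined to a two-day national consumption survey:
# log-normal residue concentrations with a configurable non-detect fraction,
# gamma-distributed consumption amounts, sparse food x substance coverage,
# survey weights, and HTS tables with a planted potency ordering. Every
# substance carries a planted decision-tree branch and exposure tier, and the
# concentration scale is calibrated so the planted tier lands at a known
# multiple of the substance's threshold — so downstream test failures indicate
# pipeline bugs, not generator noise.

plant_branches <- c("excluded", "genotoxic", "op_phosphate", "carbamate",
                    "cramer_I", "cramer_II", "cramer_III", "no_structure")

#' Parameters of a synthetic study scenario
#'
#' Defaults mirror the real study design the generator stands in for:
#' 3,819 survey subjects with two non-consecutive recall days each, and
#' survey weights drawn uniform in `[0.5, 2]` then normalized. The
#' planted design cycles each substance class suffix through the
#' decision-tree branches, alternating high/low exposure tiers; a
#' high-tier substance is calibrated to `high_ratio` times its
#' threshold (its TTC, or the 0.5 ug/kg bw/day cutoff for excluded and
#' structure-less substances) and a low-tier one to `low_ratio` times.
#'
#' @param n_subjects Number of survey subjects.
#' @param n_days Recall days per subject.
#' @param n_per_class Substances per class suffix (PPP/ORG/TOX/CHE/PAR).
#' @param n_foods,n_commodities Consumed foods and raw commodities
#'   (`n_foods >= n_commodities` so every commodity is reachable).
#' @param nondetect_fraction Probability that a concentration sample is
#'   censored (reported below LOD or LOQ), in `[0, 1]`.
#' @param sigma_log Log-scale SD of the log-normal concentrations.
#' @param high_ratio,low_ratio Planted mean-exposure-to-threshold ratios
#'   of the two tiers.
#' @param n_samples Analytical samples per substance x commodity pair.
#' @param not_tested_fraction Fraction of substances left untested per
#'   HTS model.
#' @param cutoff Exposure cutoff (ug/kg bw/day) anchoring the excluded
#'   and structure-less plants.
#' @param seed Integer seed; the scenario is deterministic given
#'   `(params, seed)`.
#' @return A `scenario_params` list, validated.
#' @export
scenario_params <- function(n_subjects = 3819, n_days = 2, n_per_class = 3,
                            n_foods = 12, n_commodities = 8,
                            nondetect_fraction = 0.3, sigma_log = 0.4,
                            high_ratio = 10, low_ratio = 0.1,
                            n_samples = 8, not_tested_fraction = 0.2,
                            cutoff = 0.5, seed = 1) {
  p <- list(n_subjects = n_subjects, n_days = n_days, n_per_class = n_per_class,
            n_foods = n_foods, n_commodities = n_commodities,
            nondetect_fraction = nondetect_fraction, sigma_log = sigma_log,
            high_ratio = high_ratio, low_ratio = low_ratio,
            n_samples = n_samples, not_tested_fraction = not_tested_fraction,
            cutoff = cutoff, seed = seed)
  counts <- c(p$n_subjects, p$n_days, p$n_per_class, p$n_foods,
              p$n_commodities, p$n_samples)
  stopifnot(all(counts >= 1),
            p$nondetect_fraction >= 0, p$nondetect_fraction <= 1,
            p$sigma_log > 0, p$high_ratio > 0, p$low_ratio > 0,
            p$not_tested_fraction >= 0, p$not_tested_fraction < 1,
            p$cutoff > 0, p$n_foods >= p$n_commodities)
  class(p) <- "scenario_params"
  p
}

# Planted design: cycle branches within each class suffix, alternate tiers.
plant_design <- function(n_per_class) {
  plants <- tidyr::expand_grid(class = substance_classes,
                               idx = seq_len(n_per_class))
  k <- nrow(plants)
  plants$branch <- plant_branches[(seq_len(k) - 1L) %% length(plant_branches) + 1L]
  plants$tier <- ifelse(seq_len(k) %% 2L == 1L, "high", "low")
  plants$code <- sprintf("S%03d-%s", seq_len(k), plants$class)
  plants[, c("code", "class", "branch", "tier")]
}

plant_threshold <- function(branch, cutoff) {
  tiers <- ttc_tiers()
  unname(vapply(branch, function(b) {
    switch(b,
      genotoxic = tiers[["genotoxic"]],
      op_phosphate = ,
      carbamate = tiers[["op_carbamate"]],
      cramer_I = tiers[["cramer_I"]],
      cramer_II = tiers[["cramer_II"]],
      cramer_III = tiers[["cramer_III"]],
      excluded = ,
      no_structure = cutoff
    )
  }, numeric(1)))
}

plant_intended_list <- function(branch, tier) {
  dplyr::case_when(
    branch == "no_structure" ~ "unevaluated",
    tier == "high" & branch == "excluded" ~ "ttc_excluded_priority",
    tier == "high" ~ "ttc_priority",
    TRUE ~ "not_priority"
  )
}

structure_pools <- list(
  op_phosphate = c(
    "CCOP(=O)(OCC)OCC", "COP(=O)(OC)OC", "CCOP(=O)(OCC)Oc1ccccc1",
    "COP(=O)(OC)Oc1ccc([N+](=O)[O-])cc1", "CCCOP(=O)(OCCC)OCCC",
    "COP(=O)(OC)OC=C(Cl)Cl"
  ),
  carbamate_disubstituted = c(
    "CN(C)C(=O)Oc1ccccc1", "CCN(CC)C(=O)OC", "CN(C)C(=O)OCC",
    "CCN(C)C(=O)Oc1ccccc1", "CN(C)C(=O)Oc1ccc(C)cc1", "CCN(CC)C(=O)Oc1ccccn1"
  ),
  neither = c(
    "CCO", "c1ccccc1", "CC(C)O", "CCCCO", "CC(=O)C", "c1ccncc1",
    "CCOCC", "CC(=O)OCC", "Cc1ccccc1", "OCC(O)CO", "CCCCCC",
    "CC(C)Cc1ccc(C)cc1"
  )
)

#' Draw structures that provably match (or avoid) the filter patterns
#'
#' Samples SMILES from curated template pools: organophosphates that hit
#' the literal phosphate pattern, disubstituted carbamates that hit the
#' literal carbamate pattern, and plain structures that miss both
#' patterns even in relaxed mode. Pattern membership is asserted at
#' draw time.
#'
#' @param branch `"op_phosphate"`, `"carbamate_disubstituted"` or
#'   `"neither"`.
#' @param n Number of structures to draw (with replacement).
#' @return Character vector of SMILES.
#' @export
#' @examples
#' set.seed(1)
#' generate_structures("neither", 2)
generate_structures <- function(branch = c("op_phosphate",
                                           "carbamate_disubstituted",
                                           "neither"),
                                n = 1) {
  branch <- match.arg(branch)
  pool <- structure_pools[[branch]]
  smiles <- sample(pool, n, replace = TRUE)
  hits <- match_op_carbamate(smiles,
                             mode = if (branch == "neither") "relaxed" else "literal")
  ok <- switch(branch,
    op_phosphate = all(hits$phosphate_hit),
    carbamate_disubstituted = all(hits$carbamate_hit),
    neither = !any(hits$phosphate_hit | hits$carbamate_hit)
  )
  if (!ok) stop("structure pool violates its pattern contract", call. = FALSE)
  smiles
}

# Alert profile realizing (or avoiding) the two-of-three consensus.
plant_alerts <- function(genotoxic) {
  ames <- ca <- c(FALSE, FALSE, FALSE)
  if (genotoxic) {
    endpoint <- sample(c("ames", "ca"), 1)
    pos <- sample(3, sample(2:3, 1))
    if (endpoint == "ames") ames[pos] <- TRUE else ca[pos] <- TRUE
  } else {
    # at most one positive model per endpoint keeps the consensus negative
    if (stats::runif(1) < 0.3) ames[sample(3, 1)] <- TRUE
    if (stats::runif(1) < 0.3) ca[sample(3, 1)] <- TRUE
  }
  stats::setNames(c(ames, ca), c(paste("alert", "ames", alert_models, sep = "_"),
                                 paste("alert", "ca", alert_models, sep = "_")))
}

#' Generate a complete synthetic scenario
#'
#' Produces the five input tables plus a truth table recording, per
#' substance, the planted decision-tree branch, exposure tier, intended
#' priority-list membership and the generating concentration
#' parameters. Deterministic given `(params, seed)`.
#'
#' The concentration scale of each substance is calibrated against the
#' generated consumption pattern: the survey-weighted mean exposure per
#' unit concentration is computed for the substance's commodities, and
#' the log-normal concentration mean is set so the expected upper-bound
#' mean exposure equals `tier_ratio x threshold`. Censoring limits are
#' placed at 0.8x (LOD) and 1.2x (LOQ) of the substance's mean
#' concentration, so upper-bound substitution is scale-preserving in
#' expectation while the lower bound loses the censored mass.
#'
#' @param params A [scenario_params()] object.
#' @return List with `concentrations`, `consumption`, `translation`,
#'   `annotations`, `hts_tables` (one tibble per prediction model),
#'   `domain_map`, and `truth_table`.
#' @export
generate_scenario <- function(params = scenario_params()) {
  stopifnot(inherits(params, "scenario_params"))
  set.seed(params$seed)
  plants <- plant_design(params$n_per_class)

  # --- survey population -------------------------------------------------
  subjects <- tibble::tibble(
    subject_id = sprintf("SUBJ%05d", seq_len(params$n_subjects)),
    body_weight = round(pmin(pmax(stats::rnorm(params$n_subjects, 70, 12), 25), 120), 1),
    survey_weight = stats::runif(params$n_subjects, 0.5, 2)
  )
  subjects$survey_weight <- subjects$survey_weight / mean(subjects$survey_weight)

  # --- foods, commodities, translation -----------------------------------
  foods <- sprintf("F%02d", seq_len(params$n_foods))
  commodities <- sprintf("RAC%02d", seq_len(params$n_commodities))
  translation <- tibble::tibble(
    food_code = foods,
    commodity_code = commodities[(seq_len(params$n_foods) - 1L) %%
                                   params$n_commodities + 1L],
    percent = sample(seq(40, 100, by = 5), params$n_foods, replace = TRUE)
  )
  secondary <- stats::runif(params$n_foods) < 0.5
  if (any(secondary)) {
    translation <- dplyr::bind_rows(translation, tibble::tibble(
      food_code = foods[secondary],
      commodity_code = vapply(which(secondary), function(j) {
        sample(setdiff(commodities, translation$commodity_code[j]), 1)
      }, character(1)),
      percent = sample(seq(10, 50, by = 5), sum(secondary), replace = TRUE)
    ))
  }
  translation <- validate_translation(
    translation[order(translation$food_code, translation$commodity_code), ])

  # --- consumption diary: two recall days, gamma amounts ------------------
  diary <- tidyr::expand_grid(
    subject_id = subjects$subject_id,
    day = seq_len(params$n_days),
    food_code = foods
  )
  eaten <- stats::runif(nrow(diary)) < 0.5 | diary$food_code == foods[1]
  diary <- diary[eaten, ]
  diary$amount <- round(stats::rgamma(nrow(diary), shape = 2, scale = 60), 1)
  consumption <- validate_consumption(
    dplyr::left_join(diary, subjects, by = "subject_id"))

  # --- substance x commodity coverage and calibration ---------------------
  plants$threshold <- plant_threshold(plants$branch, params$cutoff)
  plants$ratio <- ifelse(plants$tier == "high", params$high_ratio, params$low_ratio)
  plants$target_exposure <- plants$ratio * plants$threshold

  coverage <- lapply(seq_len(nrow(plants)), function(i) {
    sample(commodities, sample(1:2, 1))
  })

  # survey-weighted mean exposure per unit concentration, per commodity
  unit_conc <- tibble::tibble(
    substance_code = paste0("UNIT-", commodities), commodity_code = commodities,
    result_type = "VAL", value = 1, lod = NA_real_, loq = NA_real_
  )
  base <- summarize_exposure(
    per_subject_oim(consumption, unit_conc, translation, "upper_bound"),
    "upper_bound"
  )
  base_per_commodity <- stats::setNames(
    base$weighted_mean, sub("^UNIT-", "", base$substance_code))

  plants$base_exposure <- vapply(coverage, function(cc) {
    sum(base_per_commodity[cc])
  }, numeric(1))
  if (any(plants$base_exposure <= 0)) {
    stop("unrealizable plant: substance(s) measured only in unconsumed commodities: ",
         paste(plants$code[plants$base_exposure <= 0], collapse = ", "),
         call. = FALSE)
  }
  plants$conc_mean <- plants$target_exposure / plants$base_exposure
  plants$conc_meanlog <- log(plants$conc_mean) - params$sigma_log^2 / 2

  samples <- dplyr::bind_rows(lapply(seq_len(nrow(plants)), function(i) {
    cc <- coverage[[i]]
    n <- params$n_samples * length(cc)
    val <- stats::rlnorm(n, plants$conc_meanlog[i], params$sigma_log)
    censored <- stats::runif(n) < params$nondetect_fraction
    rtype <- ifelse(!censored, "VAL",
                    ifelse(stats::runif(n) < 0.5, "ND_LOD", "ND_LOQ"))
    tibble::tibble(
      substance_code = plants$code[i],
      commodity_code = rep(cc, each = params$n_samples),
      result_type = rtype,
      value = ifelse(rtype == "VAL", val, NA_real_),
      lod = 0.8 * plants$conc_mean[i],
      loq = 1.2 * plants$conc_mean[i]
    )
  }))
  concentrations <- validate_concentrations(samples)

  # --- annotations realizing each planted branch --------------------------
  ann_rows <- lapply(seq_len(nrow(plants)), function(i) {
    b <- plants$branch[i]
    smiles <- switch(b,
      no_structure = NA_character_,
      op_phosphate = generate_structures("op_phosphate"),
      carbamate = generate_structures("carbamate_disubstituted"),
      generate_structures("neither")
    )
    alerts <- if (b %in% c("excluded", "no_structure")) {
      stats::setNames(rep(NA, 6), alert_columns())
    } else {
      plant_alerts(genotoxic = b == "genotoxic")
    }
    cramer <- switch(b,
      cramer_I = "I", cramer_II = "II", cramer_III = "III",
      genotoxic = sample(cramer_classes, 1),
      op_phosphate = , carbamate = "III",
      NA_character_
    )
    flags <- if (b == "excluded") {
      paste(sample(exclusion_categories, sample(1:2, 1)), collapse = ";")
    } else NA_character_
    tibble::as_tibble(c(
      list(code = plants$code[i], name = paste("substance", plants$code[i]),
           smiles = smiles, exclusion_flags = flags),
      as.list(alerts),
      list(cramer_class = cramer)
    ))
  })
  annotations <- validate_annotations(dplyr::bind_rows(ann_rows))

  # --- HTS tables with a planted potency order ----------------------------
  priority_codes <- plants$code[plant_intended_list(plants$branch, plants$tier) ==
                                  "ttc_priority"]
  potency_order <- sample(priority_codes)
  hts <- generate_hts_tables(plants$code, potency_order,
                             not_tested_fraction = params$not_tested_fraction)

  truth <- tibble::tibble(
    code = plants$code,
    branch = plants$branch,
    tier = plants$tier,
    intended_list = plant_intended_list(plants$branch, plants$tier),
    threshold = plants$threshold,
    target_exposure = plants$target_exposure,
    conc_meanlog = plants$conc_meanlog,
    potency_rank = match(plants$code, potency_order)
  )

  list(concentrations = concentrations, consumption = consumption,
       translation = translation, annotations = annotations,
       hts_tables = hts$tables, domain_map = hts$domain_map,
       truth_table = truth)
}

hts_model_specs <- tibble::tibble(
  model_id = c("toxpi_endocrine", "zebrafish_pct", "cell_ac50",
               "celegans_rank", "devtox_lel"),
  readout_type = c("composite_score", "percent", "ac50", "rank", "lel"),
  domain = c("E", "D", "C", "D", "H")
)

#' Generate HTS result tables with a planted potency ordering
#'
#' One table per readout type (composite score, percent-of-maximum,
#' AC50, rank, LEL). Within each table the raw values are
#' monotone-consistent with the planted order: concentrations (AC50,
#' LEL) increase with decreasing potency, the other readouts decrease.
#' A configurable fraction of substances is left `not_tested` per model
#' (absence of data), distinct from `not_active` (an observed
#' negative).
#'
#' @param substances All substance codes in the study.
#' @param potency_order Strict ranking (most potent first) of the
#'   subset of substances planted as active.
#' @param not_tested_fraction Fraction of substances untested per model.
#' @param seed Optional integer seed; `NULL` uses the current RNG
#'   state (as inside [generate_scenario()]).
#' @return List with `tables` (named list of validated HTS tibbles, one
#'   per model) and `domain_map` (tibble `model_id, domain`).
#' @export
generate_hts_tables <- function(substances, potency_order,
                                not_tested_fraction = 0.2, seed = NULL) {
  stopifnot(!anyDuplicated(potency_order),
            all(potency_order %in% substances))
  if (!is.null(seed)) set.seed(seed)
  tables <- lapply(seq_len(nrow(hts_model_specs)), function(m) {
    spec <- hts_model_specs[m, ]
    n_skip <- floor(not_tested_fraction * length(substances))
    untested <- sample(substances, n_skip)
    active <- setdiff(potency_order, untested)  # keeps planted order
    inactive <- setdiff(substances, c(active, untested))
    k <- length(active)
    raw <- switch(spec$readout_type,
      composite_score = seq(10, 1, length.out = max(k, 2))[seq_len(k)],
      percent = seq(95, 20, length.out = max(k, 2))[seq_len(k)],
      ac50 = 0.05 * 3^(seq_len(k) - 1),
      rank = seq_len(k),
      lel = 0.1 * 2.5^(seq_len(k) - 1)
    )
    validate_hts(tibble::tibble(
      model_id = spec$model_id,
      substance_code = c(active, inactive, untested),
      readout_type = spec$readout_type,
      value = c(raw, rep(NA_real_, length(inactive) + length(untested))),
      status = c(rep("active", k), rep("not_active", length(inactive)),
                 rep("not_tested", length(untested)))
    ))
  })
  names(tables) <- hts_model_specs$model_id
  list(tables = tables,
       domain_map = hts_model_specs[, c("model_id", "domain")])
}

#' Write a generated scenario to a directory
#'
#' Writes the five input tables plus `truth_table.csv` and
#' `domain_map.csv` as CSV; HTS tables are stacked into one file.
#'
#' @param scenario Output of [generate_scenario()].
#' @param dir Target directory (created if needed).
#' @return Named vector of the paths written, invisibly.
#' @export
write_scenario <- function(scenario, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  paths <- c(
    concentrations = file.path(dir, "concentrations.csv"),
    consumption = file.path(dir, "consumption.csv"),
    translation = file.path(dir, "translation.csv"),
    annotations = file.path(dir, "annotations.csv"),
    hts = file.path(dir, "hts_results.csv"),
    domain_map = file.path(dir, "domain_map.csv"),
    truth_table = file.path(dir, "truth_table.csv")
  )
  write_table(scenario$concentrations, paths["concentrations"])
  write_table(scenario$consumption, paths["consumption"])
  write_table(scenario$translation, paths["translation"])
  write_table(scenario$annotations, paths["annotations"])
  write_table(dplyr::bind_rows(scenario$hts_tables), paths["hts"])
  write_table(scenario$domain_map, paths["domain_map"])
  write_table(scenario$truth_table, paths["truth_table"])
  invisible(paths)
}
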