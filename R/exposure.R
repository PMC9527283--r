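# Chronic dietary exposure under the observed-individual-mean (OIM) model.
#
# Units are kept strict throughout: consumption in g/day, concentrations in
# mg/kg commodity, body weight in kg, so 1 g x 1 mg/kg = 1 ug and intakes come
# out in ug/kg bw/day without conversion factors.

#' Resolve a possibly censored concentration under a bound scenario
#'
#' Quantified samples keep their value in both scenarios. Non-detects
#' are set to 0 in the lower-bound scenario; in the upper-bound scenario
#' a sample below the detection limit is set to its LOD and a sample
#' below the quantification limit to its LOQ.
#'
#' @param samples Validated concentration tibble
#'   (see [validate_concentrations()]).
#' @param scenario `"lower_bound"` or `"upper_bound"`.
#' @return Numeric vector of resolved concentrations (mg/kg), one per row.
#' @export
#' @examples
#' s <- tibble::tibble(substance_code = "A-PPP", commodity_code = "C1",
#'                     result_type = "ND_LOD", value = NA, lod = 0.01, loq = 0.03)
#' resolve_concentration(s, "upper_bound")  # 0.01
resolve_concentration <- function(samples, scenario = c("lower_bound", "upper_bound")) {
  scenario <- match.arg(scenario)
  out <- samples$value
  nd_lod <- samples$result_type == "ND_LOD"
  nd_loq <- samples$result_type == "ND_LOQ"
  if (scenario == "lower_bound") {
    out[nd_lod | nd_loq] <- 0
  } else {
    out[nd_lod] <- samples$lod[nd_lod]
    out[nd_loq] <- samples$loq[nd_loq]
  }
  out
}

#' Pool samples to one concentration per substance and commodity
#'
#' Scenario-resolves every sample, then takes the arithmetic mean over
#' all samples of each substance x commodity pair — the chronic-exposure
#' pooling convention used by the engine.
#'
#' @inheritParams resolve_concentration
#' @return Tibble `substance_code, commodity_code, concentration`
#'   (mg/kg) with one row per pair.
#' @export
mean_concentrations <- function(samples, scenario = c("lower_bound", "upper_bound")) {
  scenario <- match.arg(scenario)
  samples$resolved <- resolve_concentration(samples, scenario)
  dplyr::summarise(
    dplyr::group_by(samples, .data$substance_code, .data$commodity_code),
    concentration = mean(.data$resolved),
    .groups = "drop"
  )
}

#' Translate consumed foods to raw commodity amounts
#'
#' Expands each `(subject, day, food, amount)` record through the
#' translation table: a food mapping to a commodity at `percent` yields
#' `amount * percent / 100` grams of that commodity. Foods absent from
#' the table contribute nothing and are returned as a diagnostic, never
#' dropped silently.
#'
#' @param consumption Validated consumption tibble.
#' @param translation Validated translation tibble.
#' @return List with `commodities` (tibble `subject_id, day,
#'   commodity_code, amount` in g/day, summed within subject-day) and
#'   `untranslated` (tibble `food_code, n_records` of diary foods with
#'   no translation entry).
#' @export
translate_consumption <- function(consumption, translation) {
  untrans <- dplyr::count(
    dplyr::filter(consumption, !.data$food_code %in% translation$food_code),
    .data$food_code, name = "n_records"
  )
  expanded <- dplyr::inner_join(consumption, translation,
                                by = "food_code", relationship = "many-to-many")
  commodities <- dplyr::summarise(
    dplyr::group_by(expanded, .data$subject_id, .data$day, .data$commodity_code),
    amount = sum(.data$amount * .data$percent / 100),
    .groups = "drop"
  )
  list(commodities = commodities, untranslated = untrans)
}

#' Daily intake of one substance for one subject-day
#'
#' `sum(amount_g * concentration_mg_per_kg) / body_weight_kg`, in
#' ug/kg bw/day.
#'
#' @param amounts Commodity amounts consumed that day (g).
#' @param concentrations Matching resolved concentrations (mg/kg).
#' @param body_weight Subject body weight (kg).
#' @return Scalar intake in ug/kg bw/day.
#' @export
#' @examples
#' daily_intake(70, 0.1, 70)  # 0.1
daily_intake <- function(amounts, concentrations, body_weight) {
  stopifnot(length(amounts) == length(concentrations))
  if (body_weight <= 0) stop("body_weight must be > 0", call. = FALSE)
  if (any(amounts < 0) || any(concentrations < 0)) {
    stop("amounts and concentrations must be >= 0", call. = FALSE)
  }
  if (length(amounts) == 0L) return(0)
  sum(amounts * concentrations) / body_weight
}

#' Observed individual mean over a subject's survey days
#'
#' The chronic-exposure statistic per subject: the arithmetic mean of
#' the subject's daily intakes over their recorded days.
#'
#' @param day_intakes Numeric vector of per-day intakes (ug/kg bw/day),
#'   one per recorded day; must be non-empty.
#' @return Scalar OIM intake.
#' @export
#' @examples
#' oim(c(1, 2))  # 1.5
oim <- function(day_intakes) {
  if (length(day_intakes) == 0L) {
    stop("oim() needs at least one recorded day", call. = FALSE)
  }
  mean(day_intakes)
}

#' Survey-weighted mean
#'
#' @param x Values.
#' @param w Positive weights aligned with `x`.
#' @return `sum(w * x) / sum(w)`.
#' @export
weighted_mean <- function(x, w) {
  check_weights(x, w)
  sum(w * x) / sum(w)
}

#' Survey-weighted quantiles of the cumulative-weight distribution
#'
#' Hazen-type inverse of the weighted empirical distribution: the
#' quantile at probability `p` is the smallest sorted value whose
#' cumulative weight reaches `p * sum(w)`, averaged with the next value
#' when the target falls exactly on a cumulative-weight boundary. With
#' equal weights this is the classical type 2 sample quantile.
#'
#' This step-inverse definition (rather than grid interpolation between
#' sorted values) is what makes the censoring-scenario ordering exact:
#' it is monotone under pointwise dominance, so a lower-bound intake
#' vector that is everywhere below its upper-bound counterpart can
#' never produce a larger quantile, whatever the survey weights.
#'
#' @param x Values.
#' @param w Positive weights aligned with `x`.
#' @param probs Probabilities in `[0, 1]`.
#' @return Numeric vector of quantiles, one per element of `probs`.
#' @export
#' @examples
#' weighted_quantile(1:100, rep(1, 100), 0.95)  # 95.5
weighted_quantile <- function(x, w, probs) {
  check_weights(x, w)
  stopifnot(all(probs >= 0 & probs <= 1))
  o <- order(x)
  x <- x[o]
  w <- w[o]
  n <- length(x)
  s <- cumsum(w)
  vapply(probs, function(p) {
    target <- p * s[n]
    i <- which(s >= target * (1 - 1e-12))[1]
    on_boundary <- abs(s[i] - target) <= 1e-12 * s[n]
    if (on_boundary && i < n) (x[i] + x[i + 1]) / 2 else x[i]
  }, numeric(1))
}

check_weights <- function(x, w) {
  if (length(x) != length(w)) {
    stop("weights must align with values (", length(w), " vs ", length(x), ")",
         call. = FALSE)
  }
  if (length(x) == 0L) stop("empty value set", call. = FALSE)
  if (any(w <= 0) || anyNA(w)) stop("weights must be positive", call. = FALSE)
  invisible(TRUE)
}

#' Per-subject OIM intakes for every substance
#'
#' The full engine for one censoring scenario: pools concentrations per
#' substance x commodity ([mean_concentrations()]), translates the diary
#' to commodity amounts ([translate_consumption()]), accumulates each
#' subject's intake and divides by their number of recorded days and
#' body weight. Subjects who never consume a contributing food are
#' retained with an OIM of 0 — the chronic population distribution
#' includes non-consumers.
#'
#' @param consumption,concentrations,translation Validated input tibbles.
#' @inheritParams resolve_concentration
#' @return Tibble `substance_code, subject_id, oim, body_weight,
#'   survey_weight` with one row per substance x subject.
#' @export
per_subject_oim <- function(consumption, concentrations, translation,
                            scenario = c("lower_bound", "upper_bound")) {
  scenario <- match.arg(scenario)
  subjects <- dplyr::summarise(
    dplyr::group_by(consumption, .data$subject_id),
    body_weight = .data$body_weight[1],
    survey_weight = .data$survey_weight[1],
    n_days = dplyr::n_distinct(.data$day),
    .groups = "drop"
  )
  conc <- mean_concentrations(concentrations, scenario)
  commodities <- translate_consumption(consumption, translation)$commodities
  loads <- dplyr::inner_join(commodities, conc,
                             by = "commodity_code", relationship = "many-to-many")
  totals <- dplyr::summarise(
    dplyr::group_by(loads, .data$substance_code, .data$subject_id),
    total_ug = sum(.data$amount * .data$concentration),
    .groups = "drop"
  )
  grid <- tidyr::expand_grid(
    substance_code = unique(concentrations$substance_code),
    subjects
  )
  out <- dplyr::left_join(grid, totals, by = c("substance_code", "subject_id"))
  out$total_ug[is.na(out$total_ug)] <- 0
  out$oim <- out$total_ug / (out$n_days * out$body_weight)
  out[, c("substance_code", "subject_id", "oim", "body_weight", "survey_weight")]
}

#' Summarize per-subject intakes into population exposure estimates
#'
#' Survey-weighted mean, median and 95th percentile of the OIM
#' distribution per substance.
#'
#' @param oim_tbl Output of [per_subject_oim()].
#' @param scenario Scenario label carried into the output.
#' @return Tibble `substance_code, scenario, weighted_mean,
#'   weighted_median, weighted_p95, n_subjects` (all exposure columns in
#'   ug/kg bw/day).
#' @export
summarize_exposure <- function(oim_tbl, scenario) {
  dplyr::summarise(
    dplyr::group_by(oim_tbl, .data$substance_code),
    scenario = scenario,
    weighted_mean = weighted_mean(.data$oim, .data$survey_weight),
    weighted_median = weighted_quantile(.data$oim, .data$survey_weight, 0.5),
    weighted_p95 = weighted_quantile(.data$oim, .data$survey_weight, 0.95),
    n_subjects = dplyr::n(),
    .groups = "drop"
  )
}

#' Chronic exposure estimates for one or both bound scenarios
#'
#' Convenience wrapper running [per_subject_oim()] +
#' [summarize_exposure()] for `"lower_bound"`, `"upper_bound"` or both.
#'
#' @inheritParams per_subject_oim
#' @param scenario `"lower_bound"`, `"upper_bound"` or `"both"`.
#' @return Tibble of exposure summaries, stacked over scenarios.
#' @export
compute_exposure <- function(consumption, concentrations, translation,
                             scenario = c("upper_bound", "lower_bound", "both")) {
  scenario <- match.arg(scenario)
  wanted <- if (scenario == "both") c("lower_bound", "upper_bound") else scenario
  dplyr::bind_rows(lapply(wanted, function(sc) {
    summarize_exposure(
      per_subject_oim(consumption, concentrations, translation, sc), sc
    )
  }))
}
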