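# Shared domain vocabulary and table validators.
#
# All tables are plain tibbles with documented columns; validators enforce the
# invariants once at the boundary so downstream stages can assume clean input.

#' Domain vocabulary
#'
#' Constant vectors shared across the pipeline: substance class suffixes,
#' TTC exclusion categories, genotoxicity alert columns, censoring result
#' types, HTS readout types, and the five TTC tiers (ug/kg bw/day).
#'
#' @name vocabulary
#' @keywords internal
NULL

substance_classes <- c("PPP", "ORG", "TOX", "CHE", "PAR")

exclusion_categories <- c(
  "inorganic", "metal_containing", "mixture", "bioaccumulating",
  "aflatoxin_like"
)

alert_models <- c("derek", "iss", "oasis")
alert_endpoints <- c("ames", "ca")

# six (endpoint, model) alert columns, e.g. alert_ames_derek
alert_columns <- function() {
  as.vector(outer(alert_endpoints, alert_models,
                  function(e, m) paste("alert", e, m, sep = "_")))
}

cramer_classes <- c("I", "II", "III")

result_types <- c("VAL", "ND_LOD", "ND_LOQ")

readout_types <- c("composite_score", "percent", "ac50", "rank", "lel")

hts_statuses <- c("active", "not_active", "not_tested")

#' TTC tiers of the decision tree
#'
#' Named vector of the five thresholds of toxicological concern, in
#' ug/kg bw/day: genotoxic 0.0025, organophosphate/carbamate 0.3,
#' Cramer class III 1.5, class II 9, class I 30.
#'
#' @return Named numeric vector.
#' @export
#' @examples
#' ttc_tiers()
ttc_tiers <- function() {
  c(genotoxic = 0.0025, op_carbamate = 0.3,
    cramer_III = 1.5, cramer_II = 9, cramer_I = 30)
}

priority_lists <- c("ttc_priority", "ttc_excluded_priority",
                    "not_priority", "unevaluated")

fail_rows <- function(ok, what, detail = NULL) {
  if (all(ok)) return(invisible(TRUE))
  bad <- which(!ok)
  shown <- utils::head(bad, 10L)
  msg <- sprintf("%s: rows %s%s", what, paste(shown, collapse = ", "),
                 if (length(bad) > 10L) sprintf(" (and %d more)", length(bad) - 10L) else "")
  if (!is.null(detail)) msg <- paste0(msg, "\n", detail)
  stop(msg, call. = FALSE)
}

require_columns <- function(tbl, cols, what) {
  missing <- setdiff(cols, names(tbl))
  if (length(missing) > 0L) {
    stop(sprintf("%s: missing mandatory column(s): %s",
                 what, paste(missing, collapse = ", ")), call. = FALSE)
  }
  invisible(TRUE)
}

substance_class_of <- function(code) {
  suffix <- sub(".*-", "", code)
  ifelse(suffix %in% substance_classes, suffix, NA_character_)
}

#' Validate a concentration monitoring table
#'
#' One row per analytical sample: `substance_code`, `commodity_code`,
#' `result_type` (`VAL` quantified, `ND_LOD` below detection, `ND_LOQ`
#' below quantification), `value` (mg/kg, present iff `VAL`), `lod`,
#' `loq` (mg/kg, optional). Checks the censoring invariants: a `VAL` row
#' carries a non-negative value and no censored row does; `ND_LOD`
#' requires `lod`, `ND_LOQ` requires `loq`; `lod <= loq` where both
#' present.
#'
#' @param tbl A data frame of concentration samples.
#' @return The validated tibble, invisibly classed as-is.
#' @export
validate_concentrations <- function(tbl) {
  tbl <- tibble::as_tibble(tbl)
  require_columns(tbl, c("substance_code", "commodity_code", "result_type",
                         "value", "lod", "loq"), "concentration table")
  fail_rows(tbl$result_type %in% result_types,
            "concentration table: unknown result_type")
  is_val <- tbl$result_type == "VAL"
  fail_rows(!is_val | (!is.na(tbl$value) & tbl$value >= 0),
            "concentration table: VAL rows need a non-negative value")
  fail_rows(is_val | is.na(tbl$value),
            "concentration table: censored rows must not carry a value")
  fail_rows(tbl$result_type != "ND_LOD" | !is.na(tbl$lod),
            "concentration table: ND_LOD rows need lod")
  fail_rows(tbl$result_type != "ND_LOQ" | !is.na(tbl$loq),
            "concentration table: ND_LOQ rows need loq")
  both <- !is.na(tbl$lod) & !is.na(tbl$loq)
  fail_rows(!both | tbl$lod <= tbl$loq,
            "concentration table: lod must not exceed loq")
  tbl
}

#' Validate a consumption diary table
#'
#' One row per food eaten by one subject on one survey day:
#' `subject_id`, `day`, `food_code`, `amount` (g/day), `body_weight`
#' (kg), `survey_weight`. Body weight and survey weight must be constant
#' within subject; amounts non-negative, weights positive.
#'
#' @param tbl A data frame of consumption records.
#' @return The validated tibble.
#' @export
validate_consumption <- function(tbl) {
  tbl <- tibble::as_tibble(tbl)
  require_columns(tbl, c("subject_id", "day", "food_code", "amount",
                         "body_weight", "survey_weight"), "consumption table")
  fail_rows(!is.na(tbl$amount) & tbl$amount >= 0,
            "consumption table: amount must be >= 0")
  fail_rows(!is.na(tbl$body_weight) & tbl$body_weight > 0,
            "consumption table: body_weight must be > 0")
  fail_rows(!is.na(tbl$survey_weight) & tbl$survey_weight > 0,
            "consumption table: survey_weight must be > 0")
  per_subject <- dplyr::summarise(
    dplyr::group_by(tbl, .data$subject_id),
    n_bw = dplyr::n_distinct(.data$body_weight),
    n_sw = dplyr::n_distinct(.data$survey_weight),
    .groups = "drop"
  )
  bad <- per_subject$subject_id[per_subject$n_bw > 1L | per_subject$n_sw > 1L]
  if (length(bad) > 0L) {
    stop("consumption table: body_weight/survey_weight not constant within subject(s): ",
         paste(utils::head(bad, 5L), collapse = ", "), call. = FALSE)
  }
  tbl
}

#' Validate a food translation table
#'
#' Maps consumed foods to raw agricultural commodities: `food_code`,
#' `commodity_code`, `percent` (share of the consumed food mass
#' attributed to the commodity; may exceed 100 for concentrated foods).
#' Pairs must be unique and percentages strictly positive.
#'
#' @param tbl A data frame of translation entries.
#' @return The validated tibble.
#' @export
validate_translation <- function(tbl) {
  tbl <- tibble::as_tibble(tbl)
  require_columns(tbl, c("food_code", "commodity_code", "percent"),
                  "translation table")
  fail_rows(!is.na(tbl$percent) & tbl$percent > 0,
            "translation table: percent must be > 0")
  key <- paste(tbl$food_code, tbl$commodity_code, sep = "\r")
  fail_rows(!duplicated(key),
            "translation table: duplicate (food_code, commodity_code) pair")
  tbl
}

#' Validate a substance annotation table
#'
#' One row per substance: `code` (with a class suffix in
#' PPP/ORG/TOX/CHE/PAR), `name`, `smiles` (NA when no representative
#' structure), `exclusion_flags` (semicolon-separated subset of the TTC
#' exclusion categories; empty/NA means none), the six genotoxicity
#' alert booleans `alert_{ames,ca}_{derek,iss,oasis}` (all-NA row means
#' no alert evaluation), and `cramer_class` (I/II/III or NA).
#'
#' A Cramer class is required whenever a structure is present and no
#' exclusion flag is set (the decision tree would otherwise dead-end).
#' Alert columns must be either all present or all absent per row.
#'
#' @param tbl A data frame of annotations.
#' @return The validated tibble.
#' @export
validate_annotations <- function(tbl) {
  tbl <- tibble::as_tibble(tbl)
  require_columns(tbl, c("code", "name", "smiles", "exclusion_flags",
                         alert_columns(), "cramer_class"),
                  "annotation table")
  fail_rows(!duplicated(tbl$code), "annotation table: duplicate substance code")
  fail_rows(!is.na(substance_class_of(tbl$code)),
            "annotation table: code suffix not in PPP/ORG/TOX/CHE/PAR")
  flags <- parse_exclusion_flags(tbl$exclusion_flags)
  bad_flag <- vapply(flags, function(f) length(setdiff(f, exclusion_categories)) > 0L,
                     logical(1))
  fail_rows(!bad_flag, "annotation table: unknown exclusion flag")
  fail_rows(is.na(tbl$cramer_class) | tbl$cramer_class %in% cramer_classes,
            "annotation table: cramer_class must be I, II or III")
  amat <- as.matrix(tbl[alert_columns()])
  n_na <- rowSums(is.na(amat))
  fail_rows(n_na == 0L | n_na == length(alert_columns()),
            "annotation table: alert profile must be fully present or fully absent")
  excluded <- lengths(flags) > 0L
  fail_rows(is.na(tbl$smiles) | excluded | !is.na(tbl$cramer_class),
            "annotation table: structured non-excluded substances need a Cramer class")
  tbl
}

#' Validate a high-throughput screening result table
#'
#' One row per (model, substance): `model_id`, `substance_code`,
#' `readout_type` (composite_score/percent/ac50/rank/lel), `value`,
#' `status` (active/not_active/not_tested). A value is present iff the
#' row is active; AC50/LEL values are strictly positive concentrations
#' (uM); ranks are positive integers unique within a model.
#'
#' @param tbl A data frame of raw HTS records.
#' @return The validated tibble.
#' @export
validate_hts <- function(tbl) {
  tbl <- tibble::as_tibble(tbl)
  require_columns(tbl, c("model_id", "substance_code", "readout_type",
                         "value", "status"), "HTS table")
  fail_rows(tbl$readout_type %in% readout_types, "HTS table: unknown readout_type")
  fail_rows(tbl$status %in% hts_statuses, "HTS table: unknown status")
  active <- tbl$status == "active"
  fail_rows(active == !is.na(tbl$value),
            "HTS table: value must be present iff status is active")
  conc <- tbl$readout_type %in% c("ac50", "lel") & active
  fail_rows(!conc | tbl$value > 0, "HTS table: ac50/lel values must be > 0")
  rnk <- tbl$readout_type == "rank" & active
  fail_rows(!rnk | (tbl$value >= 1 & tbl$value == round(tbl$value)),
            "HTS table: ranks must be positive integers")
  for (m in unique(tbl$model_id[rnk])) {
    rv <- tbl$value[rnk & tbl$model_id == m]
    if (anyDuplicated(rv)) {
      stop(sprintf("HTS table: duplicate rank within model %s", m), call. = FALSE)
    }
  }
  tbl
}

# "a;b" -> list(c("a","b")); NA/"" -> character(0)
parse_exclusion_flags <- function(x) {
  lapply(x, function(s) {
    if (is.na(s) || !nzchar(s)) character(0)
    else strsplit(s, ";", fixed = TRUE)[[1]]
  })
}

format_exclusion_flags <- function(flags) {
  vapply(flags, paste, character(1), collapse = ";")
}
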