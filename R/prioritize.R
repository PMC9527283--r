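# Hazard quotients, the two priority lists, and the screening subset.

#' Hazard quotient
#'
#' Ratio of an exposure estimate to the substance's TTC; dimensionless.
#'
#' @param exposure Exposure statistic (ug/kg bw/day), > 0.
#' @param ttc_value Assigned TTC (ug/kg bw/day), > 0.
#' @return `exposure / ttc_value`.
#' @export
#' @examples
#' hazard_quotient(0.005, 0.0025)  # 2
hazard_quotient <- function(exposure, ttc_value) {
  if (any(is.na(ttc_value)) || any(ttc_value <= 0)) {
    stop("ttc_value must be > 0", call. = FALSE)
  }
  if (any(is.na(exposure)) || any(exposure < 0)) {
    stop("exposure must be >= 0", call. = FALSE)
  }
  exposure / ttc_value
}

#' Partition substances into the priority lists
#'
#' Joins exposure statistics with TTC assignments and derives the
#' workflow's four mutually exclusive lists:
#' \describe{
#'   \item{ttc_priority}{TTC assigned and hazard quotient strictly
#'     above 1 — exposure exceeds the threshold.}
#'   \item{ttc_excluded_priority}{TTC-excluded substance with exposure
#'     at or above `cutoff` (inclusive).}
#'   \item{unevaluated}{no representative structure, regardless of
#'     exposure — awaiting further prioritization.}
#'   \item{not_priority}{everything else.}
#' }
#'
#' @param exposures Tibble `substance_code, exposure_stat` (the
#'   configured scenario/statistic, ug/kg bw/day).
#' @param assignments TTC assignments from [assign_ttc()].
#' @param cutoff Exposure cutoff for TTC-excluded substances
#'   (ug/kg bw/day, default 0.5).
#' @return Tibble `substance_code, exposure_stat, outcome, ttc_value,
#'   exclusion_reason, hq, list`, one row per assignment.
#' @export
build_lists <- function(exposures, assignments, cutoff = 0.5) {
  stopifnot(cutoff > 0)
  require_columns(exposures, c("substance_code", "exposure_stat"), "exposures")
  rec <- dplyr::left_join(assignments, exposures, by = "substance_code")
  needs_exposure <- rec$outcome %in% c("ttc_assigned", "excluded")
  missing <- needs_exposure & is.na(rec$exposure_stat)
  if (any(missing)) {
    stop("no exposure estimate for assigned/excluded substance(s): ",
         paste(utils::head(rec$substance_code[missing], 10L), collapse = ", "),
         call. = FALSE)
  }
  rec$hq <- ifelse(rec$outcome == "ttc_assigned",
                   rec$exposure_stat / rec$ttc_value, NA_real_)
  rec$list <- dplyr::case_when(
    rec$outcome == "no_structure" ~ "unevaluated",
    rec$outcome == "ttc_assigned" & rec$hq > 1 ~ "ttc_priority",
    rec$outcome == "excluded" & rec$exposure_stat >= cutoff ~ "ttc_excluded_priority",
    TRUE ~ "not_priority"
  )
  rec[, c("substance_code", "exposure_stat", "outcome", "ttc_value",
          "exclusion_reason", "hq", "list")]
}

#' Default per-TTC-class screening counts
#'
#' The screening subset takes the highest-HQ substances per TTC class:
#' 10 from the genotoxicity class (0.0025), 2 each from 0.3 and 1.5;
#' the configuration extends the same count of 2 to the classes 9 and
#' 30 for symmetry (they are typically empty among HQ > 1 substances).
#'
#' @return Named numeric vector mapping TTC value to count.
#' @export
default_screening_counts <- function() {
  c("0.0025" = 10, "0.3" = 2, "1.5" = 2, "9" = 2, "30" = 2)
}

#' Select the HTS screening subset
#'
#' Within each TTC class, `ttc_priority` records are ranked by
#' descending hazard quotient (ties: descending exposure, then
#' ascending substance code) and the top `per_class_counts[class]` are
#' taken — fewer when the class is smaller. The result is ordered by
#' TTC ascending, then HQ descending.
#'
#' @param records Priority records from [build_lists()]; only
#'   `ttc_priority` rows are eligible.
#' @param per_class_counts Named vector mapping TTC value (formatted as
#'   by `format()`, e.g. `"0.0025"`) to the number of substances to screen.
#' @return Ordered tibble of selected records, with a `screen_rank`
#'   column (1 = first within its class).
#' @export
select_for_screening <- function(records, per_class_counts = default_screening_counts()) {
  eligible <- records[records$list == "ttc_priority", ]
  if (any(is.na(eligible$hq))) {
    stop("ttc_priority records must carry an HQ", call. = FALSE)
  }
  eligible <- eligible[order(eligible$ttc_value, -eligible$hq,
                             -eligible$exposure_stat, eligible$substance_code), ]
  grouped <- dplyr::group_by(eligible, .data$ttc_value)
  ranked <- dplyr::mutate(grouped, screen_rank = dplyr::row_number())
  out <- dplyr::ungroup(dplyr::filter(ranked, {
    key <- format(.data$ttc_value[1], trim = TRUE)
    k <- if (key %in% names(per_class_counts)) per_class_counts[[key]] else 0
    .data$screen_rank <= k
  }))
  out[order(out$ttc_value, -out$hq, -out$exposure_stat, out$substance_code), ]
}
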