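# Readers and writers for the five CSV dialects plus the priority report.
#
# All files are UTF-8, comma-separated, "." decimal. Readers validate on load
# and fail loudly with row numbers; the single defined demotion is an invalid
# SMILES, which keeps the record but drops the structure (such substances stay
# in the run as "awaiting further prioritization").

# Check the header before parsing so a missing mandatory column yields a
# format error rather than a parser warning.
read_csv_checked <- function(path, col_types, required, what) {
  hdr <- names(readr::read_csv(path, n_max = 0, show_col_types = FALSE,
                               col_types = readr::cols(.default = readr::col_character())))
  missing <- setdiff(required, hdr)
  if (length(missing) > 0L) {
    stop(sprintf("%s: missing mandatory column(s): %s",
                 what, paste(missing, collapse = ", ")), call. = FALSE)
  }
  readr::read_csv(path, col_types = col_types)
}

concentration_cols <- readr::cols(
  substance_code = readr::col_character(),
  commodity_code = readr::col_character(),
  result_type = readr::col_character(),
  value = readr::col_double(),
  lod = readr::col_double(),
  loq = readr::col_double()
)

#' Read a concentration monitoring table
#'
#' Flat CSV modelled on SSD1-coded monitoring submissions:
#' `substance_code, commodity_code, result_type, value, lod, loq`
#' (mg/kg). See [validate_concentrations()] for the row invariants.
#'
#' @param path CSV file path.
#' @return Validated tibble of concentration samples.
#' @export
read_concentration_table <- function(path) {
  tbl <- read_csv_checked(path, concentration_cols,
                          c("substance_code", "commodity_code", "result_type",
                            "value", "lod", "loq"), "concentration table")
  validate_concentrations(tbl)
}

#' Read an individual consumption diary
#'
#' CSV columns: `subject_id, day, food_code, amount` (g/day),
#' `body_weight` (kg), `survey_weight`.
#'
#' @param path CSV file path.
#' @return Validated tibble of consumption records.
#' @export
read_consumption_table <- function(path) {
  tbl <- read_csv_checked(path, required = c("subject_id", "day", "food_code",
                                             "amount", "body_weight", "survey_weight"),
                          what = "consumption table", col_types = readr::cols(
    subject_id = readr::col_character(),
    day = readr::col_integer(),
    food_code = readr::col_character(),
    amount = readr::col_double(),
    body_weight = readr::col_double(),
    survey_weight = readr::col_double()
  ))
  validate_consumption(tbl)
}

#' Read a food translation table
#'
#' CSV columns: `food_code, commodity_code, percent` (share of consumed
#' food mass attributed to the raw commodity).
#'
#' @param path CSV file path.
#' @return Validated tibble of translation entries.
#' @export
read_translation_table <- function(path) {
  tbl <- read_csv_checked(path, required = c("food_code", "commodity_code", "percent"),
                          what = "translation table", col_types = readr::cols(
    food_code = readr::col_character(),
    commodity_code = readr::col_character(),
    percent = readr::col_double()
  ))
  validate_translation(tbl)
}

#' Read a substance annotation table
#'
#' CSV columns: `code, name, smiles, exclusion_flags`, the six alert
#' booleans `alert_{ames,ca}_{derek,iss,oasis}`, and `cramer_class`.
#' SMILES are validated at load; a string that does not parse demotes
#' the record to "no structure" with a warning rather than aborting,
#' so structure-less entries remain in the run.
#'
#' @param path CSV file path.
#' @return Validated tibble of annotations.
#' @export
read_annotations <- function(path) {
  tbl <- read_csv_checked(path, required = c("code", "name", "smiles",
                                             "exclusion_flags", alert_columns(),
                                             "cramer_class"),
                          what = "annotation table", col_types = readr::cols(
    code = readr::col_character(),
    name = readr::col_character(),
    smiles = readr::col_character(),
    exclusion_flags = readr::col_character(),
    cramer_class = readr::col_character(),
    .default = readr::col_logical()
  ))
  require_columns(tbl, c("code", "smiles"), "annotation table")
  has_smiles <- !is.na(tbl$smiles) & nzchar(tbl$smiles)
  invalid <- has_smiles & !is_valid_smiles(tbl$smiles)
  if (any(invalid)) {
    warning(sprintf(
      "annotation table: %d unparseable SMILES demoted to no-structure (%s)",
      sum(invalid),
      paste(utils::head(tbl$code[invalid], 5L), collapse = ", ")
    ), call. = FALSE)
    tbl$smiles[invalid] <- NA_character_
  }
  validate_annotations(tbl)
}

#' Read a high-throughput screening result table
#'
#' CSV columns: `model_id, substance_code, readout_type, value, status`.
#'
#' @param path CSV file path.
#' @return Validated tibble of raw HTS records.
#' @export
read_hts_table <- function(path) {
  tbl <- read_csv_checked(path, required = c("model_id", "substance_code",
                                             "readout_type", "value", "status"),
                          what = "HTS table", col_types = readr::cols(
    model_id = readr::col_character(),
    substance_code = readr::col_character(),
    readout_type = readr::col_character(),
    value = readr::col_double(),
    status = readr::col_character()
  ))
  validate_hts(tbl)
}

#' Write any pipeline table as CSV
#'
#' Thin deterministic writer (UTF-8, "." decimal, no timestamps) so that
#' repeated runs with the same seed produce byte-identical files.
#'
#' @param tbl Data frame.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_table <- function(tbl, path) {
  readr::write_csv(tbl, path)
  invisible(path)
}

#' Write the three-part priority report
#'
#' Splits completed priority records into the workflow's output lists:
#' `ttc_applicable_priorities.csv` (TTC assigned and hazard quotient
#' above 1), `ttc_excluded_priorities.csv` (TTC-excluded substances over
#' the exposure cutoff), and `unevaluated.csv` (no representative
#' structure, awaiting further prioritization). A `run_metadata.csv`
#' with the seed, config hash and per-list counts accompanies them.
#'
#' @param records Priority records from [build_lists()].
#' @param dir Output directory (created if needed).
#' @param seed,config_hash Provenance fields recorded in the metadata
#'   file; pass `NA` when not applicable.
#' @return Named character vector of the files written, invisibly.
#' @export
write_priority_report <- function(records, dir, seed = NA, config_hash = NA) {
  required <- c("substance_code", "exposure_stat", "outcome", "ttc_value",
                "hq", "list")
  require_columns(records, required, "priority records")
  in_ttc <- records$list == "ttc_priority"
  if (any(in_ttc & is.na(records$hq))) {
    stop("priority records: ttc_priority members must carry an HQ (missing for ",
         paste(utils::head(records$substance_code[in_ttc & is.na(records$hq)], 5L),
               collapse = ", "), ")", call. = FALSE)
  }
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  parts <- list(
    ttc_applicable_priorities = records[records$list == "ttc_priority", ],
    ttc_excluded_priorities = records[records$list == "ttc_excluded_priority", ],
    unevaluated = records[records$list == "unevaluated", ]
  )
  paths <- character(0)
  for (nm in names(parts)) {
    p <- file.path(dir, paste0(nm, ".csv"))
    readr::write_csv(parts[[nm]], p)
    paths[nm] <- p
  }
  meta <- tibble::tibble(
    field = c("seed", "config_hash", "n_records",
              paste0("n_", names(parts)), "n_not_priority"),
    value = as.character(c(seed, config_hash, nrow(records),
                           vapply(parts, nrow, integer(1)),
                           sum(records$list == "not_priority")))
  )
  mp <- file.path(dir, "run_metadata.csv")
  readr::write_csv(meta, mp)
  paths["run_metadata"] <- mp
  invisible(paths)
}
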