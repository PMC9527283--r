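# The four-step TTC decision tree: exclusion rules, two-of-three genotoxicity
# consensus, organophosphate/carbamate substructures, Cramer classes.
# Steps short-circuit in order 1 -> 2 -> 3 -> 4.

#' Evaluate the TTC exclusion criteria
#'
#' A substance is excluded from the TTC approach when any exclusion
#' category applies (inorganic, metal-containing, mixture,
#' bioaccumulating, aflatoxin-like) — no safe exposure threshold can be
#' derived for these classes. All set flags are reported.
#'
#' @param annotations Validated annotation tibble.
#' @return Tibble `code, excluded, exclusion_reason` (reason is a
#'   semicolon-joined list of the set flags, NA when none).
#' @export
check_exclusion <- function(annotations) {
  flags <- parse_exclusion_flags(annotations$exclusion_flags)
  excluded <- lengths(flags) > 0L
  tibble::tibble(
    code = annotations$code,
    excluded = excluded,
    exclusion_reason = ifelse(excluded, format_exclusion_flags(flags), NA_character_)
  )
}

#' Two-of-three cross-model genotoxicity consensus
#'
#' An endpoint (Ames mutagenicity or chromosome damage) is positive when
#' at least two of the three alert models (DEREK, ISS, OASIS) flag it;
#' a substance is considered genotoxic when either endpoint is positive.
#'
#' @param ames Logical vector or matrix-like of the three Ames model
#'   flags; for the vectorized form pass the annotation tibble to
#'   [assign_ttc()] instead.
#' @param ca The three chromosome-damage model flags.
#' @return Logical scalar: genotoxic by consensus?
#' @export
#' @examples
#' genotoxicity_consensus(c(TRUE, TRUE, FALSE), c(FALSE, FALSE, FALSE))
genotoxicity_consensus <- function(ames, ca) {
  stopifnot(length(ames) == 3L, length(ca) == 3L,
            !anyNA(ames), !anyNA(ca))
  sum(ames) >= 2L || sum(ca) >= 2L
}

# vectorized consensus over the six annotation alert columns; NA where the
# alert profile is absent
consensus_rows <- function(annotations) {
  ames <- as.matrix(annotations[paste("alert", "ames", alert_models, sep = "_")])
  ca <- as.matrix(annotations[paste("alert", "ca", alert_models, sep = "_")])
  rowSums(ames) >= 2L | rowSums(ca) >= 2L
}

#' Run the TTC decision tree over an annotation table
#'
#' Sequential short-circuit evaluation per substance:
#' \enumerate{
#'   \item any exclusion flag set -> outcome `excluded`;
#'   \item no representative structure -> outcome `no_structure`
#'     (retained, awaiting further prioritization);
#'   \item genotoxic by the two-of-three consensus -> TTC 0.0025;
#'   \item organophosphate or carbamate substructure -> TTC 0.3;
#'   \item Cramer class III -> 1.5, II -> 9, I -> 30 ug/kg bw/day.
#' }
#' `decision_path` records every step actually evaluated, stopping at
#' the first that fires.
#'
#' @param annotations Validated annotation tibble.
#' @param mode Substructure matching mode, `"literal"` (default) or
#'   `"relaxed"`; see [op_carbamate_patterns()].
#' @return Tibble `substance_code, outcome, ttc_value, decision_path,
#'   exclusion_reason`; `ttc_value` (ug/kg bw/day) is non-NA iff
#'   `outcome == "ttc_assigned"`.
#' @export
#' @examples
#' ann <- tibble::tibble(
#'   code = "S1-PPP", name = "x", smiles = "CCO", exclusion_flags = NA,
#'   alert_ames_derek = FALSE, alert_ames_iss = FALSE, alert_ames_oasis = FALSE,
#'   alert_ca_derek = FALSE, alert_ca_iss = FALSE, alert_ca_oasis = FALSE,
#'   cramer_class = "I"
#' )
#' assign_ttc(ann)$ttc_value  # 30
assign_ttc <- function(annotations, mode = c("literal", "relaxed")) {
  mode <- match.arg(mode)
  annotations <- validate_annotations(annotations)
  n <- nrow(annotations)
  tiers <- ttc_tiers()

  excl <- check_exclusion(annotations)
  has_structure <- !is.na(annotations$smiles)
  has_alerts <- !is.na(annotations$alert_ames_derek)
  genotoxic <- consensus_rows(annotations)

  needs_alerts <- !excl$excluded & has_structure
  if (any(needs_alerts & !has_alerts)) {
    stop("annotation incomplete: structured, non-excluded substances without ",
         "an alert profile: ",
         paste(utils::head(annotations$code[needs_alerts & !has_alerts], 5L),
               collapse = ", "), call. = FALSE)
  }

  # substructure step only matters for structured, non-excluded, non-genotoxic
  need_match <- needs_alerts & !genotoxic
  phosphate <- carbamate <- rep(FALSE, n)
  if (any(need_match)) {
    hits <- match_op_carbamate(annotations$smiles[need_match], mode)
    phosphate[need_match] <- hits$phosphate_hit
    carbamate[need_match] <- hits$carbamate_hit
  }
  op_hit <- phosphate | carbamate

  outcome <- character(n)
  ttc_value <- rep(NA_real_, n)
  path <- character(n)
  for (i in seq_len(n)) {
    if (excl$excluded[i]) {
      outcome[i] <- "excluded"
      path[i] <- paste0("exclusion:", excl$exclusion_reason[i])
    } else if (!has_structure[i]) {
      outcome[i] <- "no_structure"
      path[i] <- "exclusion:clear>structure:absent"
    } else if (genotoxic[i]) {
      outcome[i] <- "ttc_assigned"
      ttc_value[i] <- tiers[["genotoxic"]]
      path[i] <- "exclusion:clear>genotoxicity:positive"
    } else if (op_hit[i]) {
      outcome[i] <- "ttc_assigned"
      ttc_value[i] <- tiers[["op_carbamate"]]
      path[i] <- paste0("exclusion:clear>genotoxicity:negative>op_carbamate:",
                        if (phosphate[i] && carbamate[i]) "phosphate+carbamate"
                        else if (phosphate[i]) "phosphate" else "carbamate")
    } else {
      cls <- annotations$cramer_class[i]
      if (is.na(cls)) {
        stop("annotation incomplete: substance ", annotations$code[i],
             " reaches the Cramer step without a Cramer class", call. = FALSE)
      }
      outcome[i] <- "ttc_assigned"
      ttc_value[i] <- tiers[[paste0("cramer_", cls)]]
      path[i] <- paste0("exclusion:clear>genotoxicity:negative>",
                        "op_carbamate:miss>cramer:", cls)
    }
  }

  tibble::tibble(
    substance_code = annotations$code,
    outcome = outcome,
    ttc_value = ttc_value,
    decision_path = path,
    exclusion_reason = excl$exclusion_reason
  )
}
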