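# Builders for small in-code fixtures shared across the suite.

alert_names <- function() {
  c("alert_ames_derek", "alert_ames_iss", "alert_ames_oasis",
    "alert_ca_derek", "alert_ca_iss", "alert_ca_oasis")
}

# One annotation row. ames/ca are length-3 logicals (DEREK, ISS, OASIS);
# NULL leaves the whole alert profile absent.
make_annotation <- function(code = "S001-PPP", smiles = "CCO",
                            flags = NA_character_,
                            ames = c(FALSE, FALSE, FALSE),
                            ca = c(FALSE, FALSE, FALSE),
                            cramer = "III", name = "test substance") {
  alerts <- if (is.null(ames)) rep(NA, 6) else c(ames, ca)
  tibble::as_tibble(c(
    list(code = code, name = name, smiles = smiles, exclusion_flags = flags),
    stats::setNames(as.list(alerts), alert_names()),
    list(cramer_class = cramer)
  ))
}

make_sample <- function(substance = "S001-PPP", commodity = "RAC01",
                        result_type = "VAL", value = 0.2,
                        lod = NA_real_, loq = NA_real_) {
  tibble::tibble(substance_code = substance, commodity_code = commodity,
                 result_type = result_type,
                 value = if (result_type == "VAL") value else NA_real_,
                 lod = lod, loq = loq)
}

# Minimal hand-sized study: 2 subjects, 2 days, 2 foods, 2 commodities.
tiny_study <- function() {
  consumption <- tibble::tibble(
    subject_id = rep(c("A", "B"), each = 4),
    day = rep(c(1L, 1L, 2L, 2L), 2),
    food_code = rep(c("bread", "juice"), 4),
    amount = c(100, 50, 120, 0, 80, 200, 90, 10),
    body_weight = rep(c(70, 50), each = 4),
    survey_weight = rep(c(1.2, 0.8), each = 4)
  )
  translation <- tibble::tibble(
    food_code = c("bread", "bread", "juice"),
    commodity_code = c("wheat", "water", "apple"),
    percent = c(70, 30, 110)
  )
  concentrations <- dplyr::bind_rows(
    make_sample("S001-PPP", "wheat", "VAL", 0.2),
    make_sample("S001-PPP", "wheat", "ND_LOD", lod = 0.01, loq = 0.03),
    make_sample("S001-PPP", "apple", "VAL", 0.05),
    make_sample("S002-ORG", "apple", "ND_LOQ", lod = 0.02, loq = 0.06)
  )
  list(consumption = consumption, translation = translation,
       concentrations = concentrations)
}
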