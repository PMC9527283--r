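# Seeded generators: determinism, plant realizability, censoring limits, and
# monotone-consistent HTS tables.

test_that("identical params and seed give byte-identical written scenarios", {
  p <- scenario_params(n_subjects = 20, seed = 5)
  d1 <- withr::local_tempdir()
  d2 <- withr::local_tempdir()
  f1 <- write_scenario(generate_scenario(p), d1)
  f2 <- write_scenario(generate_scenario(p), d2)
  for (nm in names(f1)) {
    expect_identical(readLines(f1[[nm]]), readLines(f2[[nm]]), label = nm)
  }
  # and a different seed actually changes the data
  p2 <- scenario_params(n_subjects = 20, seed = 6)
  expect_false(identical(generate_scenario(p2)$concentrations,
                         generate_scenario(p)$concentrations))
})

test_that("generated tables pass their validators and match the study design", {
  p <- scenario_params(n_subjects = 30, seed = 2)
  sc <- generate_scenario(p)
  expect_silent(validate_concentrations(sc$concentrations))
  expect_silent(validate_consumption(sc$consumption))
  expect_silent(validate_translation(sc$translation))
  expect_silent(validate_annotations(sc$annotations))
  # every subject contributes exactly two recall days
  per_subject <- dplyr::count(dplyr::distinct(sc$consumption, subject_id, day),
                              subject_id)
  expect_true(all(per_subject$n == 2L))
  expect_equal(nrow(per_subject), 30L)
  # every consumed food translates to at least one commodity
  expect_true(all(unique(sc$consumption$food_code) %in% sc$translation$food_code))
})

test_that("planted annotations realize their decision-tree branch", {
  sc <- generate_scenario(scenario_params(n_subjects = 15, seed = 8))
  ann <- sc$annotations
  truth <- sc$truth_table
  for (i in seq_len(nrow(truth))) {
    a <- ann[ann$code == truth$code[i], ]
    b <- truth$branch[i]
    if (b == "no_structure") {
      expect_true(is.na(a$smiles))
    } else if (b == "excluded") {
      expect_true(nzchar(a$exclusion_flags))
    } else {
      ames <- unlist(a[paste0("alert_ames_", c("derek", "iss", "oasis"))])
      ca <- unlist(a[paste0("alert_ca_", c("derek", "iss", "oasis"))])
      genotoxic <- sum(ames) >= 2 || sum(ca) >= 2
      expect_equal(genotoxic, b == "genotoxic", info = truth$code[i])
      hits <- match_op_carbamate(a$smiles, "relaxed")
      if (b %in% c("op_phosphate", "carbamate")) {
        lit <- match_op_carbamate(a$smiles, "literal")
        expect_true(if (b == "op_phosphate") lit$phosphate_hit else lit$carbamate_hit)
      } else if (b != "genotoxic") {
        # a planted Cramer substance must miss both patterns even relaxed
        expect_false(hits$phosphate_hit || hits$carbamate_hit)
        expect_equal(a$cramer_class, sub("cramer_", "", b))
      }
    }
  }
})

test_that("full censoring produces no quantified samples", {
  sc <- generate_scenario(scenario_params(n_subjects = 10,
                                          nondetect_fraction = 1, seed = 4))
  expect_true(all(sc$concentrations$result_type %in% c("ND_LOD", "ND_LOQ")))
  sc0 <- generate_scenario(scenario_params(n_subjects = 10,
                                           nondetect_fraction = 0, seed = 4))
  expect_true(all(sc0$concentrations$result_type == "VAL"))
})

test_that("structure templates honour their pattern contract", {
  set.seed(1)
  expect_true(all(match_op_carbamate(
    generate_structures("op_phosphate", 10), "literal")$phosphate_hit))
  expect_true(all(match_op_carbamate(
    generate_structures("carbamate_disubstituted", 10), "literal")$carbamate_hit))
  neither <- match_op_carbamate(generate_structures("neither", 10), "relaxed")
  expect_false(any(neither$phosphate_hit | neither$carbamate_hit))
})

test_that("HTS tables are monotone-consistent with the planted potency order", {
  set.seed(10)
  subs <- sprintf("S%03d-PPP", 1:12)
  order3 <- c("S004-PPP", "S001-PPP", "S009-PPP")
  res <- generate_hts_tables(subs, order3, not_tested_fraction = 0.25)
  expect_named(res$tables)
  for (tbl in res$tables) {
    act <- tbl[tbl$status == "active", ]
    pos <- match(act$substance_code, order3)
    expect_true(all(diff(pos) > 0))  # actives keep the planted order
    if (nrow(act) >= 2) {
      if (unique(tbl$readout_type) %in% c("ac50", "lel")) {
        expect_true(all(diff(act$value) > 0))   # less potent -> higher conc
      } else if (unique(tbl$readout_type) == "rank") {
        expect_equal(act$value, seq_len(nrow(act)))
      } else {
        expect_true(all(diff(act$value) < 0))   # less potent -> lower score
      }
    }
    # untested substances carry no value and are distinct from inactives
    expect_true(all(is.na(tbl$value[tbl$status != "active"])))
    expect_true(all(c("not_active", "not_tested") %in% tbl$status))
  }
})

test_that("parameter invariants are enforced at construction", {
  expect_error(scenario_params(n_subjects = 0), "counts")
  expect_error(scenario_params(nondetect_fraction = 1.2))
  expect_error(scenario_params(n_foods = 3, n_commodities = 8))
})
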