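# Hazard quotients, list partition, and the per-class screening selection.

make_records <- function(n, ttc = 0.0025, hq = NULL, seed = 1) {
  set.seed(seed)
  hq <- if (is.null(hq)) stats::runif(n, 1.01, 50) else hq
  tibble::tibble(
    substance_code = sprintf("S%03d-PPP", seq_len(n)),
    exposure_stat = hq * ttc,
    outcome = "ttc_assigned",
    ttc_value = ttc,
    exclusion_reason = NA_character_,
    hq = hq,
    list = "ttc_priority"
  )
}

test_that("hazard quotient is the exposure/TTC ratio with guarded inputs", {
  expect_equal(hazard_quotient(0.005, 0.0025), 2)
  expect_equal(hazard_quotient(0.3, 0.3), 1)
  expect_equal(hazard_quotient(0.15, 0.3), 0.5)
  expect_error(hazard_quotient(1, 0), "> 0")
  expect_error(hazard_quotient(-1, 0.3), ">= 0")
})

test_that("list membership follows HQ > 1 (strict) and cutoff >= 0.5 (inclusive)", {
  assignments <- tibble::tibble(
    substance_code = sprintf("S%d-PPP", 1:6),
    outcome = c("ttc_assigned", "ttc_assigned", "excluded", "excluded",
                "no_structure", "ttc_assigned"),
    ttc_value = c(1.5, 1.5, NA, NA, NA, 1.5),
    decision_path = "",
    exclusion_reason = c(NA, NA, "mixture", "inorganic", NA, NA)
  )
  exposures <- tibble::tibble(
    substance_code = assignments$substance_code,
    exposure_stat = c(1.8, 1.5, 0.5, 0.49, 100, 0.1)
  )
  rec <- build_lists(exposures, assignments)
  expect_equal(rec$list, c(
    "ttc_priority",       # hq = 1.2
    "not_priority",       # hq exactly 1 is NOT priority (strict >)
    "ttc_excluded_priority",  # exposure exactly at the cutoff (inclusive)
    "not_priority",       # just below the cutoff
    "unevaluated",        # no structure regardless of exposure
    "not_priority"
  ))
  expect_equal(rec$hq[1], 1.2)
  # every ttc_priority member strictly exceeds its threshold
  pri <- rec[rec$list == "ttc_priority", ]
  expect_true(all(pri$exposure_stat > pri$ttc_value))
})

test_that("an assigned substance without an exposure estimate aborts loudly", {
  assignments <- tibble::tibble(
    substance_code = "S1-PPP", outcome = "ttc_assigned", ttc_value = 1.5,
    decision_path = "", exclusion_reason = NA_character_
  )
  exposures <- tibble::tibble(substance_code = "OTHER-PPP", exposure_stat = 1)
  expect_error(build_lists(exposures, assignments), "S1-PPP")
})

test_that("the four lists partition the input and grow monotonically with exposure", {
  set.seed(7)
  for (i in 1:40) {
    n <- sample(5:40, 1)
    outcome <- sample(c("ttc_assigned", "excluded", "no_structure"), n, replace = TRUE)
    assignments <- tibble::tibble(
      substance_code = sprintf("S%03d-ORG", seq_len(n)),
      outcome = outcome,
      ttc_value = ifelse(outcome == "ttc_assigned",
                         sample(unname(ttc_tiers()), n, replace = TRUE), NA),
      decision_path = "",
      exclusion_reason = ifelse(outcome == "excluded", "mixture", NA)
    )
    exposures <- tibble::tibble(
      substance_code = assignments$substance_code,
      exposure_stat = stats::rlnorm(n, 0, 2)
    )
    rec <- build_lists(exposures, assignments)
    expect_setequal(rec$substance_code, assignments$substance_code)
    expect_equal(nrow(rec), n)  # disjoint by construction: one list per row
    expect_true(all(rec$list %in% c("ttc_priority", "ttc_excluded_priority",
                                    "not_priority", "unevaluated")))
    # scale coherence: inflating exposures never shrinks ttc_priority
    rec2 <- build_lists(dplyr::mutate(exposures, exposure_stat = exposure_stat * 3),
                        assignments)
    expect_true(all(rec$substance_code[rec$list == "ttc_priority"] %in%
                      rec2$substance_code[rec2$list == "ttc_priority"]))
  }
})

test_that("screening selection takes the top-HQ subset per class, deterministically", {
  rec <- dplyr::bind_rows(
    make_records(30, ttc = 0.0025, seed = 2),
    make_records(1, ttc = 1.5, seed = 3) |>
      dplyr::mutate(substance_code = "X001-TOX")
  )
  sel <- select_for_screening(rec)
  gtx <- sel[sel$ttc_value == 0.0025, ]
  expect_equal(nrow(gtx), 10L)
  top10 <- sort(rec$hq[rec$ttc_value == 0.0025], decreasing = TRUE)[1:10]
  expect_equal(sort(gtx$hq, decreasing = TRUE), top10)
  # a class smaller than its quota is truncated, not padded
  expect_equal(sum(sel$ttc_value == 1.5), 1L)
  # output ordered by TTC ascending then HQ descending
  expect_true(!is.unsorted(sel$ttc_value))
  expect_true(all(diff(gtx$hq) <= 0))
  # deterministic and idempotent
  expect_identical(select_for_screening(rec), sel)
  expect_identical(select_for_screening(sel), sel)
})

test_that("ties break by exposure then by substance code", {
  rec <- make_records(3, ttc = 0.3, hq = c(2, 2, 2))
  rec$exposure_stat <- c(0.6, 0.6, 0.9)
  rec$substance_code <- c("B-PPP", "A-PPP", "C-PPP")
  sel <- select_for_screening(rec, per_class_counts = c("0.3" = 2))
  expect_equal(sel$substance_code, c("C-PPP", "A-PPP"))
})
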