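# Cross-assay potency normalization and the substance x model matrix.

test_that("potency transforms are the documented monotone maps", {
  expect_equal(potency_transform(0.1, "ac50"), 1)
  expect_equal(potency_transform(85, "percent"), 85)
  expect_equal(potency_transform(1, "rank", n_active = 20), 20)
  expect_equal(potency_transform(10, "lel"), -1)
  expect_equal(potency_transform(0.7, "composite_score"), 0.7)
  expect_error(potency_transform(0, "ac50"), "> 0")
  expect_error(potency_transform(3, "rank"), "n_active")
})

test_that("normalization anchors the most potent at 100 and the least at 0", {
  # AC50s {0.1, 10, 1000} uM -> potencies {1, -1, -3} -> {100, 50, 0}
  expect_equal(normalize_dataset(potency_transform(c(0.1, 10, 1000), "ac50")),
               c(100, 50, 0))
  expect_equal(normalize_dataset(c(0.8, 0.4, 0.0)), c(100, 50, 0))
  expect_equal(normalize_dataset(5), 100)
  expect_equal(normalize_dataset(c(2, 2, 2)), c(100, 100, 100))
  expect_error(normalize_dataset(numeric(0)), "no active")
})

test_that("normalized scores preserve raw potency order and its invariances", {
  set.seed(5)
  for (i in 1:30) {
    n <- sample(2:25, 1)
    ac50 <- stats::rlnorm(n, 0, 2)
    tbl <- tibble::tibble(
      model_id = "m1", substance_code = sprintf("S%03d-PPP", seq_len(n)),
      readout_type = "ac50", value = ac50, status = "active"
    )
    norm <- normalize_hts(tbl)
    # ordering of scores is the reverse ordering of AC50s
    expect_equal(order(norm$normalized), order(-ac50))
    expect_equal(max(norm$normalized), 100)
    # changing the concentration unit shifts all logs equally: scores unchanged
    norm_nM <- normalize_hts(dplyr::mutate(tbl, value = value * 1000))
    expect_equal(norm_nM$normalized, norm$normalized, tolerance = 1e-9)
    # affine positive rescaling of a score readout leaves normalization fixed
    comp <- dplyr::mutate(tbl, readout_type = "composite_score")
    norm_c <- normalize_hts(comp)
    norm_c2 <- normalize_hts(dplyr::mutate(comp, value = 3 * value + 7))
    expect_equal(norm_c2$normalized, norm_c$normalized, tolerance = 1e-9)
  }
})

test_that("inactive and untested records are carried through, never conflated", {
  tbl <- tibble::tibble(
    model_id = "m1",
    substance_code = sprintf("S%d-PPP", 1:5),
    readout_type = "percent",
    value = c(90, 40, NA, NA, NA),
    status = c("active", "active", "not_active", "not_tested", "not_active")
  )
  norm <- normalize_hts(tbl)
  expect_equal(sum(norm$status == "not_active"), 2L)
  expect_equal(sum(norm$status == "not_tested"), 1L)
  expect_true(all(is.na(norm$normalized[norm$status != "active"])))

  selection <- tibble::tibble(substance_code = c("S3-PPP", "S1-PPP", "S6-PPP"))
  mat <- assemble_matrix(norm, selection,
                         domain_map = tibble::tibble(model_id = "m1", domain = "E"))
  expect_equal(mat$substance_code, selection$substance_code)
  expect_equal(mat[["E.m1"]], c("not_active", "100.0", "not_tested"))
  # a substance absent from every model is flagged
  expect_equal(mat$no_hts_data, c(FALSE, FALSE, TRUE))
  expect_error(
    assemble_matrix(norm, selection,
                    domain_map = tibble::tibble(model_id = "other", domain = "E")),
    "missing from domain map"
  )
})

test_that("matrix rows follow the screening order and columns group by domain", {
  sel <- tibble::tibble(substance_code = c("A-PPP", "B-PPP", "C-PPP"))
  scores <- dplyr::bind_rows(
    tibble::tibble(model_id = "zeb", substance_code = sel$substance_code,
                   readout_type = "percent", value = c(10, 50, 90),
                   status = "active"),
    tibble::tibble(model_id = "tox", substance_code = sel$substance_code,
                   readout_type = "percent", value = c(90, 50, 10),
                   status = "active")
  )
  norm <- normalize_hts(scores)
  dm <- tibble::tibble(model_id = c("zeb", "tox"), domain = c("D", "C"))
  mat <- assemble_matrix(norm, sel, dm)
  expect_equal(names(mat), c("substance_code", "no_hts_data", "C.tox", "D.zeb"))
  expect_equal(mat[["D.zeb"]], c("0.0", "50.0", "100.0"))
})
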