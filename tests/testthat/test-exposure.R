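# OIM exposure engine: censoring substitution, food translation, unit
# arithmetic, weighted summaries, and equivalence with the nested-loop oracle.

test_that("censoring substitution follows the lower/upper bound rules", {
  s <- dplyr::bind_rows(
    make_sample(result_type = "ND_LOD", lod = 0.01, loq = 0.03),
    make_sample(result_type = "ND_LOQ", lod = 0.01, loq = 0.03),
    make_sample(result_type = "VAL", value = 0.2)
  )
  expect_equal(resolve_concentration(s, "lower_bound"), c(0, 0, 0.2))
  expect_equal(resolve_concentration(s, "upper_bound"), c(0.01, 0.03, 0.2))
})

test_that("food translation conserves amounts and reports untranslated foods", {
  st <- tiny_study()
  res <- translate_consumption(st$consumption, st$translation)
  # 100 g bread -> 70 g wheat + 30 g water
  a1 <- res$commodities[res$commodities$subject_id == "A" & res$commodities$day == 1, ]
  expect_equal(a1$amount[a1$commodity_code == "wheat"], 70)
  expect_equal(a1$amount[a1$commodity_code == "water"], 30)
  # concentrated food: 110% of 50 g juice -> 55 g apple
  expect_equal(a1$amount[a1$commodity_code == "apple"], 55)
  expect_equal(nrow(res$untranslated), 0L)

  # a diary food with no translation entry shows up as a diagnostic only
  cons2 <- dplyr::bind_rows(
    st$consumption,
    tibble::tibble(subject_id = "A", day = 1L, food_code = "mystery",
                   amount = 500, body_weight = 70, survey_weight = 1.2)
  )
  res2 <- translate_consumption(cons2, st$translation)
  expect_equal(res2$untranslated$food_code, "mystery")
  expect_false("mystery" %in% res2$commodities$commodity_code)
  expect_equal(res2$commodities, res$commodities)
})

test_that("daily intake and OIM follow the unit arithmetic", {
  expect_equal(daily_intake(70, 0.1, 70), 0.1)
  expect_equal(daily_intake(numeric(0), numeric(0), 70), 0)
  expect_equal(daily_intake(c(50, 100), c(0.2, 0.1), 50), 0.4)
  expect_error(daily_intake(-1, 0.1, 70), ">= 0")
  expect_error(daily_intake(10, 0.1, 0), "body_weight")

  expect_equal(oim(c(1, 2)), 1.5)
  expect_equal(oim(0.8), 0.8)
  expect_equal(oim(c(0, 0)), 0)
  expect_error(oim(numeric(0)), "at least one")
})

test_that("weighted summaries reduce to unweighted statistics under equal weights", {
  expect_equal(weighted_mean(1:3, rep(1, 3)), 2)
  expect_equal(weighted_mean(c(0, 10), c(9, 1)), 1)
  expect_equal(weighted_quantile(1:3, rep(1, 3), 0.5), 2)
  # frozen reference: p95 of 1..100 falls on a cumulative-weight boundary
  expect_equal(weighted_quantile(1:100, rep(1, 100), 0.95), 95.5)

  set.seed(42)
  for (i in 1:25) {
    x <- stats::rlnorm(sample(3:40, 1))
    probs <- stats::runif(3)
    expect_equal(weighted_quantile(x, rep(1, length(x)), probs),
                 unname(stats::quantile(x, probs, type = 2)),
                 tolerance = 1e-12)
  }
  # monotone under pointwise dominance, whatever the weights
  for (i in 1:25) {
    n <- sample(3:30, 1)
    x <- stats::rlnorm(n)
    y <- x + stats::rlnorm(n) * stats::rbinom(n, 1, 0.5)
    w <- stats::runif(n, 0.5, 2)
    probs <- c(0.5, 0.95, stats::runif(1))
    expect_true(all(weighted_quantile(x, w, probs) <= weighted_quantile(y, w, probs)))
  }
  expect_error(weighted_quantile(1:3, 1:2, 0.5), "align")
  expect_error(weighted_mean(1:3, c(1, -1, 1)), "positive")
})

test_that("engine matches the nested-loop oracle to 1e-12 on hand-sized data", {
  st <- tiny_study()
  for (scenario in c("lower_bound", "upper_bound")) {
    eng <- per_subject_oim(st$consumption, st$concentrations,
                           st$translation, scenario)
    for (substance in unique(st$concentrations$substance_code)) {
      ref <- oracle_oim(substance, st$consumption, st$concentrations,
                        st$translation, scenario)
      sub <- eng[eng$substance_code == substance, ]
      expect_equal(stats::setNames(sub$oim, sub$subject_id), ref[sub$subject_id],
                   tolerance = 1e-12)
    }
    summ <- summarize_exposure(eng, scenario)
    s1 <- eng[eng$substance_code == "S001-PPP", ]
    expect_equal(summ$weighted_mean[summ$substance_code == "S001-PPP"],
                 oracle_weighted_mean(s1$oim, s1$survey_weight),
                 tolerance = 1e-12)
  }
})

test_that("full censoring zeroes the lower bound and pins the upper bound at the limits", {
  p <- scenario_params(n_subjects = 25, nondetect_fraction = 1, seed = 3)
  sc <- generate_scenario(p)
  expect_true(all(sc$concentrations$result_type != "VAL"))
  lower <- compute_exposure(sc$consumption, sc$concentrations, sc$translation,
                            "lower_bound")
  expect_true(all(lower$weighted_mean == 0))
  expect_true(all(lower$weighted_p95 == 0))

  # upper bound equals intake computed with all samples at their limits
  at_limits <- sc$concentrations
  at_limits$result_type <- "VAL"
  at_limits$value <- ifelse(sc$concentrations$result_type == "ND_LOD",
                            sc$concentrations$lod, sc$concentrations$loq)
  upper <- compute_exposure(sc$consumption, sc$concentrations, sc$translation,
                            "upper_bound")
  ref <- compute_exposure(sc$consumption, at_limits, sc$translation,
                          "upper_bound")
  expect_equal(upper$weighted_mean, ref$weighted_mean, tolerance = 1e-12)
})

test_that("scaling all body weights by k scales every exposure by 1/k", {
  st <- tiny_study()
  base <- per_subject_oim(st$consumption, st$concentrations, st$translation,
                          "upper_bound")
  heavier <- st$consumption
  heavier$body_weight <- heavier$body_weight * 3
  scaled <- per_subject_oim(heavier, st$concentrations, st$translation,
                            "upper_bound")
  expect_equal(scaled$oim, base$oim / 3, tolerance = 1e-12)
})

test_that("upper-bound mean converges to the calibrated analytic exposure", {
  # fully quantified substances: the only error is concentration sampling
  # noise, which shrinks with the number of analytical samples
  rel_err <- function(n_samples, seed) {
    p <- scenario_params(n_subjects = 60, nondetect_fraction = 0,
                         n_samples = n_samples, seed = seed)
    sc <- generate_scenario(p)
    ex <- compute_exposure(sc$consumption, sc$concentrations, sc$translation,
                           "upper_bound")
    j <- match(sc$truth_table$code, ex$substance_code)
    mean(abs(ex$weighted_mean[j] - sc$truth_table$target_exposure) /
           sc$truth_table$target_exposure)
  }
  coarse <- mean(vapply(1:5, function(s) rel_err(4, s), numeric(1)))
  fine <- mean(vapply(1:5, function(s) rel_err(64, s), numeric(1)))
  expect_lt(fine, coarse)
  expect_lt(fine, 0.1)
})
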