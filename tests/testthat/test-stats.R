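test_that("chi-square matches the hand-computed oracle and is zero at independence", {
  r0 <- chi_square_2x2(table2x2(10, 10, 10, 10))
  expect_equal(r0$estimate, 0)
  expect_equal(r0$effect_size_phi, 0)
  r <- chi_square_2x2(table2x2(20, 5, 5, 20))
  expect_equal(r$estimate, 18)
  expect_equal(r$effect_size_phi, 0.6)
  expect_equal(r$df, 1)
  set.seed(31)
  for (i in 1:50) {
    cells <- random_2x2_cells()
    m <- matrix(cells, 2, byrow = TRUE)
    got <- chi_square_2x2(table2x2(cells[1], cells[2], cells[3], cells[4]))
    expect_equal(got$estimate, chi2_hand(m), tolerance = 1e-12)
    expect_gte(got$estimate, 0)
  }
  expect_error(chi_square_2x2(table2x2(0, 0, 5, 5)),
               class = "climsens_degenerate_table_error")
})

test_that("phi equals |Pearson r| of the binary indicators", {
  set.seed(32)
  for (i in 1:25) {
    cells <- random_2x2_cells()
    d <- expand_2x2(cells[1], cells[2], cells[3], cells[4])
    got <- chi_square_2x2(table2x2(cells[1], cells[2], cells[3], cells[4]))
    expect_equal(got$effect_size_phi, abs(cor(d$exposure, d$outcome)),
                 tolerance = 1e-12)
  }
})

test_that("odds ratio is the cross-product with a Woolf interval", {
  expect_equal(odds_ratio_2x2(table2x2(2, 1, 1, 2))$estimate, 4)
  balanced <- odds_ratio_2x2(table2x2(10, 10, 10, 10))
  expect_equal(balanced$estimate, 1)
  expect_lt(balanced$ci_low, 1)
  expect_gt(balanced$ci_high, 1)
  r <- odds_ratio_2x2(table2x2(30, 10, 10, 30))
  expect_equal(r$estimate, 9)
  se <- sqrt(1 / 30 + 1 / 10 + 1 / 10 + 1 / 30)  # closed form
  expect_equal(r$ci_low, exp(log(9) - 1.96 * se))
  expect_equal(r$ci_high, exp(log(9) + 1.96 * se))
  expect_error(odds_ratio_2x2(table2x2(0, 5, 5, 5)),
               class = "climsens_degenerate_table_error")
  withcc <- odds_ratio_2x2(table2x2(0, 5, 5, 5), continuity = TRUE)
  expect_equal(withcc$estimate, (0.5 * 5.5) / (5.5 * 5.5))
})

test_that("pearson correlation handles exact and degenerate cases", {
  x <- c(1, 3, 7, 9, 12)
  expect_equal(pearson_correlation(x, x)$estimate, 1)
  expect_equal(pearson_correlation(x, -x)$estimate, -1)
  expect_error(pearson_correlation(x, rep(2, 5)),
               class = "climsens_value_error")
  expect_error(pearson_correlation(1:2, 1:2), class = "climsens_value_error")
})

test_that("OLS slope equals cov/var and recovers a known coefficient", {
  x <- c(0, 1, 2, 3, 4, 7)
  r <- suppressWarnings(ols_slope(x, 2 * x + 3))  # exact fit warns in summary.lm
  expect_equal(r$estimate, 2)
  expect_equal(r$df, c(1, 4))
  set.seed(33)
  for (i in 1:20) {
    n <- sample(10:60, 1)
    x <- rnorm(n)
    y <- rnorm(n, 0.5 * x)
    got <- ols_slope(x, y)
    # independent two-pass oracle
    expect_equal(got$estimate,
                 sum((x - mean(x)) * (y - mean(y))) / sum((x - mean(x))^2),
                 tolerance = 1e-12)
    expect_equal(got$df, c(1, n - 2))
  }
  # Monte-Carlo sanity: estimate near truth at large n
  set.seed(34)
  x <- rnorm(5000)
  y <- 1.5 * x + rnorm(5000)
  fit <- ols_slope(x, y)
  se <- (fit$ci_high - fit$ci_low) / (2 * qt(0.975, 4998))
  expect_lt(abs(fit$estimate - 1.5), 3 * se)
})

test_that("H-index quartile labels follow values with ties to the lower quartile", {
  expect_equal(h_index_quartiles(c(1, 2, 3, 4)), c(1L, 2L, 3L, 4L))
  expect_equal(h_index_quartiles(rep(7, 10)), rep(1L, 10))
  set.seed(35)
  h <- sample(0:50, 40, replace = TRUE)
  perm <- sample(40)
  expect_equal(h_index_quartiles(h)[perm], h_index_quartiles(h[perm]))
  expect_error(h_index_quartiles(1:3), class = "climsens_value_error")
})

test_that("logistic fit with one binary predictor reproduces the 2x2 odds ratio", {
  set.seed(36)
  for (i in 1:25) {
    cells <- random_2x2_cells()
    d <- expand_2x2(cells[1], cells[2], cells[3], cells[4])
    res <- logistic_fit(d, "outcome", "exposure")
    or <- odds_ratio_2x2(table2x2(cells[1], cells[2], cells[3], cells[4]))
    expect_equal(res[["exposure"]]$estimate, or$estimate, tolerance = 1e-7)
  }
})

test_that("logistic fit flags degenerate designs", {
  d <- expand_2x2(12, 8, 9, 11)
  d$ones <- 1
  expect_error(logistic_fit(d, "outcome", "ones"),
               class = "climsens_value_error")
  d2 <- data.frame(y = c(0, 0, 0, 1, 1, 1), x = c(0, 0, 0, 1, 1, 1))
  expect_warning(logistic_fit(d2, "y", "x"),
                 class = "climsens_separation_warning")
  # listwise deletion of missing predictors
  d3 <- expand_2x2(12, 8, 9, 11)
  d3$exposure[1] <- NA
  res <- logistic_fit(d3, "outcome", "exposure")
  expect_equal(attr(res, "n"), 39)
})

test_that("factor predictors expand against their first level", {
  set.seed(37)
  d <- data.frame(y = rbinom(200, 1, 0.4),
                  q = factor(sample(1:4, 200, replace = TRUE)))
  res <- logistic_fit(d, "y", "q")
  expect_setequal(names(res), c("q2", "q3", "q4"))
  for (r in res) expect_true(r$ci_low <= r$estimate && r$estimate <= r$ci_high)
})

test_that("the model battery runs, reports all parts, and selection drops weak terms", {
  sim <- simulate_study(synth_config(seed = 41))
  att <- validate_attributes(sim$attributes)
  prof <- sensitivity_profiles(sim$evidence, att$pathogen_id)
  assoc <- climate_associations(prof, att)
  expect_s3_class(assoc, "climsens_assoc")
  expect_equal(assoc$n, 157)
  expect_equal(assoc$n_host_known, 156)  # one unknown host dropped listwise
  expect_length(assoc$zoonotic_univariable, 3)
  expect_length(assoc$emerging_rain, 4)  # driver + 3 quartile indicators
  expect_length(assoc$emerging_climate_change, 4)
  df <- as.data.frame(assoc)
  expect_true(all(c("group", "estimate", "p_value") %in% names(df)))
  # multivariable model only ever contains univariably significant routes
  uni_p <- vapply(assoc$zoonotic_univariable, function(r) r[[1]]$p_value,
                  numeric(1))
  expect_true(all(assoc$zoonotic_multivariable_predictors %in%
                    names(uni_p)[uni_p < 0.05]))
  expect_output(print(assoc), "Zoonotic status vs any-driver sensitivity")
})

test_that("the battery recovers a strong built-in zoonotic effect", {
  sim <- simulate_study(synth_config(zoonotic_sensitivity_or = 8, seed = 42))
  att <- validate_attributes(sim$attributes)
  prof <- sensitivity_profiles(sim$evidence, att$pathogen_id)
  assoc <- climate_associations(prof, att)
  expect_lt(assoc$zoonotic_chi_square$p_value, 0.01)
  expect_gt(assoc$or_vs_human$estimate, 1)
  expect_gt(assoc$or_vs_animal$estimate, 1)
})
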