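test_that("the improvement event is cohort-specific", {
  expect_true(improved(0, 3))
  expect_true(improved(0, 4))
  expect_false(improved(0, 2))
  expect_false(improved(0, 1))
  expect_false(improved(1, 3))
  expect_true(improved(1, 4))
  expect_equal(improved(c(0, 1), c("+", "+")), c(TRUE, FALSE))
})

test_that("model-based improvement probabilities match the published table", {
  fit <- fixture_fit()
  expect_equal(improvement_prob(fit, 0, 1:3),
               c(0.4021, 0.6227, 0.8019), tolerance = 0.0005)
  expect_equal(improvement_prob(fit, 1, 1:3),
               c(0.0206, 0.0490, 0.1122), tolerance = 0.0005)
  # strictly increasing in phase for both cohorts
  expect_true(all(diff(improvement_prob(fit, 0, 1:3)) > 0))
  expect_true(all(diff(improvement_prob(fit, 1, 1:3)) > 0))
})

test_that("improvement probabilities require exactly phase and the
           baseline indicator", {
  d <- fixture_long()
  f1 <- pom(rating ~ phase, data = d)
  expect_error(improvement_prob(f1, 0, 1), "both 'phase' and 'init_rating'")
  d$junk <- rnorm(nrow(d))
  f2 <- pom(rating ~ phase + init_rating + junk, data = d)
  expect_error(improvement_prob(f2, 0, 1), "additional predictors")
})

test_that("percentile intervals are reproducible, ordered and anchored", {
  d <- fixture_long()
  ci1 <- bootstrap_improvement_ci(rating ~ phase + init_rating, d,
                                  B = 100, seed = 7)
  ci2 <- bootstrap_improvement_ci(rating ~ phase + init_rating, d,
                                  B = 100, seed = 7)
  expect_identical(ci1$lower, ci2$lower)
  expect_true(all(ci1$lower <= ci1$estimate & ci1$estimate <= ci1$upper))
  expect_true(all(ci1$lower >= 0 & ci1$upper <= 1))
  expect_equal(ci1$estimate[3], 0.8019, tolerance = 0.0005)
})

test_that("interval width shrinks with more data", {
  cfg_small <- cohort_config(thresholds = c(-1.2, 0.8, 3.0))
  cfg_big <- cohort_config(n_uncoop = 450, n_coop = 400,
                           thresholds = c(-1.2, 0.8, 3.0))
  d_small <- children_to_long(simulate_cohort(cfg_small, seed = 30))
  d_big <- children_to_long(simulate_cohort(cfg_big, seed = 30))
  w_small <- bootstrap_improvement_ci(rating ~ phase + init_rating, d_small,
                                      B = 150, seed = 1)
  w_big <- bootstrap_improvement_ci(rating ~ phase + init_rating, d_big,
                                    B = 150, seed = 1)
  expect_lt(mean(w_big$upper - w_big$lower),
            mean(w_small$upper - w_small$lower))
})

test_that("observed percentages sit inside their bootstrap intervals on
           the study counts", {
  fit <- fixture_fit()
  d <- fixture_long()
  ci <- bootstrap_improvement_ci(rating ~ phase + init_rating, d,
                                 B = 200, seed = 1)
  cmp <- improvement_comparison(fit, esba_phase_counts(), ci)
  expect_equal(cmp$predicted_pct,
               100 * c(improvement_prob(fit, 0, 1:3),
                       improvement_prob(fit, 1, 1:3)))
  expect_true(all(cmp$covered))
  # without intervals the comparison still reports both percentage columns
  cmp0 <- improvement_comparison(fit, esba_phase_counts())
  expect_null(cmp0$covered)
  expect_equal(cmp0$observed_pct[3], 84.4, tolerance = 0.05)
})

test_that("the fixture reproduction report carries its own metadata", {
  rep <- reproduce_study(B = 50, seed = 2)
  expect_equal(rep$meta$B, 50)
  expect_equal(rep$meta$seed, 2)
  expect_equal(rep$coef_table$estimate[
    rep$coef_table$term == "init_rating"], 2.48, tolerance = 0.02)
  expect_equal(rep$coef_table$estimate[
    rep$coef_table$term == "phase"], 0.90, tolerance = 0.02)
  expect_output(print(rep), "reproduction report")
})
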