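test_that("generation is reproducible and correctly shaped", {
  cfg <- cohort_config()
  r1 <- simulate_cohort(cfg, seed = 1)
  r2 <- simulate_cohort(cfg, seed = 1)
  expect_identical(r1, r2)
  r3 <- simulate_cohort(cfg, seed = 2)
  expect_false(identical(r1, r3))
  expect_equal(nrow(r1), 85L)
  expect_true(all(r1$age %in% 7:12))
  expect_true(all(r1$dmft >= 0 & r1$dmft <= 11))
  expect_true(all(r1$frankl_t0[init_rating(r1$frankl_t0) == 1] == 3))
  expect_true(all(r1$frankl_t0[1:45] %in% 1:2))  # uncooperative block
})

test_that("invalid configurations are rejected before sampling", {
  expect_error(cohort_config(thresholds = c(1, 0.5, 2)))
  expect_error(cohort_config(beta = c(phase = 1, banana = 2)),
               "unrecognised slope")
  expect_error(cohort_config(n_uncoop = 0))
})

test_that("empirical covariate marginals converge to the configuration", {
  cfg <- cohort_config(n_uncoop = 25000, n_coop = 25000)
  rec <- simulate_cohort(cfg, seed = 9)
  uncoop <- rec[init_rating(rec$frankl_t0) == 0, ]
  coop <- rec[init_rating(rec$frankl_t0) == 1, ]
  expect_lt(abs(mean(uncoop$gender == "male") - 0.689), 0.01)
  expect_lt(abs(mean(coop$gender == "male") - 0.775), 0.01)
  expect_lt(abs(mean(uncoop$medication == "yes", na.rm = TRUE) - 0.214),
            0.01)
  expect_lt(max(abs(as.numeric(prop.table(table(coop$plaque))) -
                    c(0.125, 0.30, 0.40, 0.175))), 0.01)
  expect_lt(abs(mean(is.na(uncoop$vaccination)) - 7 / 45), 0.01)
  expect_lt(abs(mean(uncoop$frankl_t0 == 1) - 6 / 45), 0.01)
  # caries burden: published quartiles and spread
  expect_equal(unname(quantile(rec$dmft, c(.25, .5, .75))), c(0, 2, 5))
  expect_lt(abs(sd(rec$dmft) - 2.9), 0.15)
})

test_that("improvement fractions obey the closed-form link at large n", {
  cfg <- cohort_config(n_uncoop = 5000, n_coop = 5000)
  rec <- simulate_cohort(cfg, seed = 13)
  long <- children_to_long(rec)
  th <- cfg$thresholds
  for (ph in 1:3) {
    for (init in 0:1) {
      rows <- long$phase == ph & long$init_rating == init
      emp <- mean(improved(init, long$rating[rows]))
      eta <- 0.90 * ph + 2.48 * init
      truth <- if (init == 0) plogis(eta - th[2]) else plogis(eta - th[3])
      expect_lt(abs(emp - truth), 0.03)
    }
  }
})

test_that("the null scenario removes all phase and cohort structure", {
  cfg <- scenario_library()$null
  rec <- simulate_cohort(cohort_config(n_uncoop = 2000, n_coop = 2000,
                                       beta = cfg$beta), seed = 5)
  long <- children_to_long(rec)
  tab <- table(long$phase, long$rating)
  expect_gt(suppressWarnings(chisq.test(tab)$p.value), 0.001)
  tab2 <- table(long$init_rating, long$rating)
  expect_gt(suppressWarnings(chisq.test(tab2)$p.value), 0.001)
})

test_that("the scenario library encodes the documented structures", {
  lib <- scenario_library()
  expect_setequal(names(lib), c("sparse", "extended", "null"))
  expect_equal(unname(lib$sparse$beta["phase"]), 0.90)
  expect_equal(unname(lib$sparse$beta["init_rating"]), 2.48)
  expect_gt(lib$extended$beta[["medication_no"]], 0)
  expect_lt(lib$extended$beta[["dmft"]], 0)
  expect_lt(lib$extended$beta[["phase_init"]], 0)
  expect_true(all(lib$null$beta == 0))
})

test_that("a child-level latent shift induces within-child dependence", {
  cfg <- cohort_config(n_uncoop = 1500, n_coop = 1500,
                       thresholds = c(-1.2, 0.8, 3.0), child_effect_sd = 2)
  rec <- simulate_cohort(cfg, seed = 6)
  long <- children_to_long(rec)
  wide <- reshape(long[, c("child_id", "phase", "rating")],
                  idvar = "child_id", timevar = "phase",
                  direction = "wide")
  dep <- cor(wide$rating.1, wide$rating.2)
  cfg0 <- cohort_config(n_uncoop = 1500, n_coop = 1500,
                        thresholds = c(-1.2, 0.8, 3.0))
  rec0 <- simulate_cohort(cfg0, seed = 6)
  long0 <- children_to_long(rec0)
  wide0 <- reshape(long0[, c("child_id", "phase", "rating")],
                   idvar = "child_id", timevar = "phase",
                   direction = "wide")
  expect_gt(dep, cor(wide0$rating.1, wide0$rating.2) + 0.1)
})
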