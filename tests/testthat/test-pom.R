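test_that("intercept-only fit recovers the closed-form marginal solution", {
  set.seed(2)
  y <- sample(1:4, 200, replace = TRUE, prob = c(0.1, 0.4, 0.4, 0.1))
  d <- data.frame(rating = y)
  fit <- pom(rating ~ 1, data = d)
  n <- tabulate(y, 4)
  expect_equal(unname(fit$theta), qlogis(cumsum(n)[1:3] / sum(n)),
               tolerance = 1e-6)
  expect_equal(fit$loglik, sum(n * log(n / sum(n))), tolerance = 1e-8)
  # a null fit predicts the marginal category proportions everywhere
  pr <- predict(fit, data.frame(x = 1))
  expect_equal(unname(pr[1, ]), n / sum(n), tolerance = 1e-6)
})

test_that("an observation with category probability 1/2 contributes log 2", {
  # thresholds (0, 1, 2), beta = 0: P(Y = 1) = plogis(0) = 1/2
  nll <- esbafit:::.pom_nll(c(0, 0, 0), X = matrix(0, 1, 0), y = 1L,
                            w = 1, K = 4L)
  expect_equal(nll, log(2), tolerance = 1e-12)
})

test_that("grouped and row-expanded data give identical fits", {
  agg <- fixture_long(aggregate = TRUE)
  fw <- pom(rating ~ phase + init_rating, agg, weights = agg$weight)
  fr <- fixture_fit()
  expect_equal(coef(fw), coef(fr), tolerance = 1e-8)
  expect_equal(fw$theta, fr$theta, tolerance = 1e-8)
  expect_equal(fw$loglik, fr$loglik, tolerance = 1e-8)
})

test_that("fit agrees with an independent ordinal-regression implementation", {
  skip_if_not_installed("MASS")
  d <- fixture_long()
  d$rating_f <- frankl_factor(d$rating)
  ref <- MASS::polr(rating_f ~ phase + init_rating, data = d, Hess = TRUE)
  fit <- fixture_fit()
  expect_equal(unname(coef(fit)), unname(coef(ref)), tolerance = 1e-4)
  expect_equal(unname(fit$theta), unname(ref$zeta), tolerance = 1e-4)
  expect_equal(fit$loglik, as.numeric(logLik(ref)), tolerance = 1e-6)
  # standard errors from the observed information agree too
  se_ref <- sqrt(diag(vcov(ref)))[1:2]
  se_fit <- sqrt(diag(vcov(fit)))[4:5]
  expect_equal(unname(se_fit), unname(se_ref), tolerance = 1e-3)
})

test_that("positive slopes push mass toward higher categories", {
  fit <- fixture_fit()
  base <- predict(fit, data.frame(phase = 2, init_rating = 0), type = "cum")
  up <- fit
  up$beta[1] <- up$beta[1] + 0.5
  shifted <- predict(up, data.frame(phase = 2, init_rating = 0), type = "cum")
  expect_true(all(shifted < base))  # P(Y <= j) drops, so P(Y >= j+1) rises
})

test_that("category probabilities lie on the simplex", {
  fit <- fixture_fit()
  nd <- expand.grid(phase = 1:3, init_rating = 0:1)
  pr <- predict(fit, nd)
  expect_true(all(pr > 0))
  expect_equal(unname(rowSums(pr)), rep(1, nrow(nd)), tolerance = 1e-12)
})

test_that("parameters are recovered from data simulated at n = 2000", {
  cfg <- cohort_config(n_uncoop = 1000, n_coop = 1000,
                       thresholds = c(-1.2, 0.8, 3.0))
  rec <- simulate_cohort(cfg, seed = 17)
  d <- children_to_long(rec)
  fit <- pom(rating ~ phase + init_rating, data = d)
  se <- sqrt(diag(vcov(fit)))
  est <- c(fit$theta, fit$beta)
  truth <- c(-1.2, 0.8, 3.0, 0.90, 2.48)
  expect_true(all(abs(est - truth) < 3 * se))
})

test_that("profile-likelihood intervals match the published final model", {
  fit <- fixture_fit()
  ci <- confint(fit, type = "profile")
  expect_equal(unname(ci["init_rating", ]), c(1.72, 3.36), tolerance = 0.01)
  expect_equal(unname(ci["phase", ]), c(0.51, 1.31), tolerance = 0.01)
  # Wald intervals are narrower here and differ from the published ones
  cw <- confint(fit, type = "wald")
  expect_lt(cw["init_rating", "upper"], ci["init_rating", "upper"])
})

test_that("Wald intervals for a null predictor cover zero at the
           nominal rate", {
  cfg <- cohort_config(thresholds = c(-1.2, 0.8, 3.0))
  cover <- logical(500)
  for (r in seq_len(500)) {
    rec <- simulate_cohort(cfg, seed = 5000 + r)
    d <- children_to_long(rec)
    d$noise <- rep(rnorm(nrow(rec)), each = 3)  # null predictor
    fit <- pom(rating ~ phase + init_rating + noise, data = d)
    if (!fit$converged) next
    ci <- confint(fit, parm = "noise", type = "wald")
    cover[r] <- ci[1] < 0 && 0 < ci[2]
  }
  expect_gte(mean(cover), 0.92)
  expect_lte(mean(cover), 0.98)
})

test_that("simulate and residuals methods are consistent with the model", {
  fit <- fixture_fit()
  nd <- expand.grid(phase = 1:3, init_rating = 0:1)
  sim <- simulate(fit, nsim = 200, seed = 9, newdata = nd)
  expect_true(all(sim %in% 1:4))
  # empirical frequencies approach predicted probabilities
  pr <- predict(fit, nd)
  emp <- t(apply(sim, 1, tabulate, 4)) / 200
  expect_lt(max(abs(emp - pr)), 0.12)

  res <- residuals(fit)
  expect_equal(nrow(res), 6 * 4)  # six covariate patterns x four categories
  expect_equal(sum(res$observed), 255)
})

test_that("fits with an unobserved response category are flagged", {
  d <- data.frame(rating = c(1, 1, 2, 2, 3, 3), phase = rep(1:3, 2))
  fit <- pom(rating ~ phase, data = d)
  expect_true(fit$degenerate)
})
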