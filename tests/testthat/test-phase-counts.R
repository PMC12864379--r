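test_that("reconstructed study counts validate and match the published rows", {
  pc <- esba_phase_counts()
  expect_s3_class(pc, "phase_counts")
  expect_true(all(rowSums(pc$uncooperative) == 45))
  expect_true(all(rowSums(pc$cooperative) == 40))
  expect_equal(unname(pc$uncooperative["phase3", ]), c(0, 7, 36, 2))
  expect_equal(unname(pc$cooperative["first_visit", ]), c(0, 0, 40, 0))
  expect_equal(unname(pc$uncooperative["phase1", ]), c(5, 24, 16, 0))
})

test_that("phase_counts rejects malformed tables", {
  expect_error(phase_counts(matrix(1, 3, 4), matrix(1, 4, 4)), "4x4")
  m <- matrix(10L, 4, 4); m2 <- m; m2[1, 1] <- 9L
  expect_error(phase_counts(m2, m), "sum to the cohort size")
  m3 <- m; m3[1, 1] <- -1L
  expect_error(phase_counts(m3, m), "non-negative")
})

test_that("count expansion produces the modelling rows and round-trips", {
  long <- counts_to_long(esba_phase_counts())
  expect_equal(nrow(long), 255L)
  expect_equal(sum(long$init_rating == 0), 135L)  # 45 children x 3 phases

  u1 <- long[long$init_rating == 0 & long$phase == 1, ]
  expect_equal(nrow(u1), 45L)
  expect_equal(sum(u1$rating == 1), 5L)

  withb <- counts_to_long(esba_phase_counts(), include_baseline = TRUE)
  expect_equal(nrow(withb), 255L + 85L)

  # regrouping the long rows reproduces every original count exactly
  pc <- esba_phase_counts()
  tab <- table(long$init_rating, long$phase, long$rating)
  for (i in 0:1) for (ph in 1:3) for (r in 1:4) {
    co <- c("uncooperative", "cooperative")[i + 1]
    expect_equal(unname(tab[as.character(i), as.character(ph),
                            as.character(r)]),
                 unname(pc[[co]][ph + 1, r]))
  }

  zero <- phase_counts(matrix(0L, 4, 4), matrix(0L, 4, 4))
  expect_equal(nrow(counts_to_long(zero)), 0L)
})

test_that("mean Frankl scores match the published trajectory", {
  pc <- esba_phase_counts()
  expect_equal(round(mean_frankl_score(pc, "uncooperative"), 1),
               c(first_visit = 1.9, phase1 = 2.2, phase2 = 2.6,
                 phase3 = 2.9))
  expect_equal(round(mean_frankl_score(pc, "cooperative"), 1),
               c(first_visit = 3.0, phase1 = 3.0, phase2 = 2.9,
                 phase3 = 3.0))
  all4 <- phase_counts(matrix(rep(c(0, 0, 0, 10), 4), 4, 4, byrow = TRUE),
                       matrix(rep(c(0, 0, 0, 10), 4), 4, 4, byrow = TRUE))
  expect_equal(unname(mean_frankl_score(all4, "cooperative")), rep(4, 4))
})

test_that("mean score is monotone under upward count shifts", {
  set.seed(11)
  for (rep in 1:25) {
    counts <- rmultinom(1, 40, runif(4))[, 1]
    lower <- which(counts > 0 & seq_len(4) < 4)
    if (!length(lower)) next
    from <- lower[sample.int(length(lower), 1)]
    higher <- (from + 1):4
    to <- higher[sample.int(length(higher), 1)]
    shifted <- counts
    shifted[from] <- shifted[from] - 1; shifted[to] <- shifted[to] + 1
    m0 <- sum(counts * 1:4) / sum(counts)
    m1 <- sum(shifted * 1:4) / sum(shifted)
    expect_gte(m1, m0)
  }
})

test_that("observed improvement percentages match the published boldface", {
  pc <- esba_phase_counts()
  expect_equal(round(observed_improvement_pct(pc, "uncooperative"), 1),
               c(phase1 = 35.6, phase2 = 60.0, phase3 = 84.4))
  expect_equal(observed_improvement_pct(pc, "cooperative"),
               c(phase1 = 2.5, phase2 = 2.5, phase3 = 7.5))
  allimp <- phase_counts(matrix(c(0, 45, 0, 0,  0, 0, 45, 0,  0, 0, 45, 0,
                                  0, 0, 0, 45), 4, 4, byrow = TRUE),
                         matrix(rep(c(0, 0, 40, 0), 4), 4, 4, byrow = TRUE))
  expect_equal(unname(observed_improvement_pct(allimp, "uncooperative")[3]),
               100)
})

test_that("transition tables come from counts only when determined", {
  pc <- esba_phase_counts()
  tab <- transition_table(pc, "cooperative", 2)
  expect_equal(unname(tab["+", ]), c(0, 4, 35, 1))
  expect_equal(sum(tab), 40)
  expect_error(transition_table(pc, "uncooperative", 2), "undetermined")

  rec <- simulate_cohort(cohort_config(), seed = 5)
  t2 <- transition_table(rec, "uncooperative", 2)
  expect_equal(sum(t2), 45)
  expect_true(all(t2[3:4, ] == 0))  # uncooperative children start at 1 or 2
})
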