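test_that("enumeration count matches brute force for small vocabularies", {
  # independent count: choose a subset, then optionally one interacting
  # predictor among the non-phase members of a subset containing phase
  brute_count <- function(p) {
    vocab <- c("phase", if (p > 1) paste0("x", seq_len(p - 1)))
    total <- 0L
    for (mask in 0:(2^p - 1)) {
      main <- vocab[bitwAnd(mask, 2^(seq_len(p) - 1)) > 0]
      total <- total + 1L
      if ("phase" %in% main)
        total <- total + length(setdiff(main, "phase"))
    }
    total
  }
  for (p in 1:5) {
    vocab <- c("phase", if (p > 1) paste0("x", seq_len(p - 1)))
    expect_equal(length(model_space(vocab)), brute_count(p))
    expect_equal(length(model_space(vocab)),
                 2^p + (p - 1) * 2^(max(p - 2, 0)) * (p >= 2))
  }
})

test_that("the ten study predictors give exactly 3328 candidates", {
  sp <- model_space(study_predictors())
  expect_equal(length(sp), 3328L)
  expect_equal(length(model_space(c("phase"))), 2L)
  expect_equal(length(model_space(c("phase", "x1", "x2"))), 12L)
  # no duplicates
  labs <- vapply(sp, esbafit:::spec_label, character(1))
  expect_false(anyDuplicated(labs) > 0)
  # every interaction spec keeps phase and the partner among main effects
  for (s in sp) {
    if (!is.null(s$interaction)) {
      expect_true("phase" %in% s$main)
      expect_true(s$interaction %in% s$main)
      expect_false(identical(s$interaction, "phase"))
    }
  }
})

test_that("vocabulary without phase falls back to the power set", {
  expect_warning(sp <- model_space(c("a", "b")), "no 'phase'")
  expect_equal(length(sp), 4L)
})

test_that("the five-way partition is disjoint, exhaustive and sized as
           published", {
  sp <- model_space(study_predictors())
  part <- partition_phase_init(sp)
  expect_equal(sum(lengths(part)), 3328L)
  expect_equal(length(part$neither), 256L)        # 2^8
  expect_equal(length(part$init_only), 256L)
  expect_equal(length(part$both_no_interaction), 256L)
  expect_equal(length(part$phase_only), 1280L)
  expect_equal(length(part$both_with_interaction), 1280L)
  expect_equal(anyDuplicated(unlist(part)), 0L)
  for (i in part$both_with_interaction)
    expect_false(is.null(sp[[i]]$interaction))
})

test_that("spec formulas reproduce the intended model terms", {
  sp <- model_space(c("phase", "init_rating"))
  labs <- vapply(sp, esbafit:::spec_label, character(1))
  f <- spec_formula(sp[[which(labs == "phase+init_rating+phase:init_rating")]])
  expect_setequal(attr(terms(f), "term.labels"),
                  c("phase", "init_rating", "phase:init_rating"))
  expect_equal(format(spec_formula(list(main = character(0),
                                        interaction = NULL))),
               "rating ~ 1")
})

test_that("minimum-BIC choice and tie-breaking follow the documented rules", {
  expect_equal(select_min_bic(c(310, 305)), 2L)
  expect_equal(select_min_bic(c(305, NA, 305), n_params = c(6, 5, 4)), 3L)
  expect_error(select_min_bic(c(NA, NA)), "no valid model")
})

test_that("the one-standard-error rule picks the most parsimonious model
           inside the interval", {
  # hand-worked case: min is model 3 (mean 350, sd 5); interval (345, 355)
  # contains model 2 (352) which has fewer parameters
  s <- list(mean = c(370, 352, 350), sd = c(9, 6, 5), n_params = c(3, 4, 5))
  expect_equal(as.integer(select_1se(s)), 2L)
  # sd = 0: interval degenerates to the minimum itself
  s0 <- list(mean = c(370, 352, 350), sd = c(9, 6, 0), n_params = c(3, 4, 5))
  expect_equal(as.integer(select_1se(s0)), 3L)
  # parsimony tie inside the interval: lower mean wins
  s2 <- list(mean = c(352, 353, 350), sd = c(6, 6, 5),
             n_params = c(4, 4, 5))
  expect_equal(as.integer(select_1se(s2)), 1L)
})
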