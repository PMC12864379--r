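#' Reproduce the study's headline analysis from the built-in counts
#'
#' Runs the complete final-model analysis on the modelling dataset
#' reconstructed from the published per-phase category counts: fits the
#' two-predictor proportional-odds model on the 255 phase-level rows,
#' reports coefficients with profile-likelihood intervals and Wald
#' p-values, the six cohort-by-phase improvement probabilities with
#' percentile-bootstrap confidence intervals, the likelihood-ratio test of
#' proportional odds, the Pearson goodness-of-fit test, and the
#' observed-versus-predicted comparison.
#'
#' @param B bootstrap replicates for the improvement intervals.
#' @param seed integer seed for the bootstrap.
#' @param level confidence level.
#' @return an object of class \code{"study_report"} (a list with elements
#'   \code{fit}, \code{coef_table}, \code{improvement}, \code{lrt},
#'   \code{gof}, \code{comparison}, \code{meta}).
#' @examples
#' \donttest{
#' rep <- reproduce_study(B = 200, seed = 1)
#' print(rep)
#' }
#' @export
reproduce_study <- function(B = 2000L, seed = 1L, level = 0.95) {
  counts <- esba_phase_counts()
  # marginal counts do not link a child's rows across phases, so the
  # bootstrap below resamples phase-level rows (stratified by cohort)
  d <- counts_to_long(counts)
  fit <- pom(rating ~ phase + init_rating, data = d)
  ci <- confint(fit, type = "profile", level = level)
  se <- sqrt(diag(vcov(fit)))[fit$K - 1 + seq_along(fit$beta)]
  z <- fit$beta / se
  coef_table <- data.frame(term = fit$coef_names, estimate = fit$beta,
                           lower = ci[, 1], upper = ci[, 2],
                           p_value = 2 * pnorm(-abs(z)))
  rownames(coef_table) <- NULL
  imp <- bootstrap_improvement_ci(rating ~ phase + init_rating, d, B = B,
                                  seed = seed, level = level)
  lrt <- lrt_prop_odds(fit, data = d)
  gof <- suppressWarnings(pearson_gof(fit, data = d))
  cmp <- improvement_comparison(fit, counts, imp)
  structure(list(fit = fit, coef_table = coef_table, improvement = imp,
                 lrt = lrt, gof = gof, comparison = cmp,
                 meta = list(B = B, seed = seed, level = level,
                             n_rows = fit$n_obs,
                             package_version =
                               as.character(utils::packageVersion("esbafit")))),
            class = "study_report")
}

#' @export
print.study_report <- function(x, digits = 4, ...) {
  cat("==== Final-model reproduction report ====\n")
  cat("n =", x$meta$n_rows, "phase-level observations; B =", x$meta$B,
      "; seed =", x$meta$seed, "\n\n")
  cat("Coefficients (profile-likelihood ", 100 * x$meta$level, "% CIs):\n",
      sep = "")
  ct <- x$coef_table
  ct[, -1] <- round(ct[, -1], digits)
  print(ct, row.names = FALSE)
  cat("\nImprovement probabilities:\n")
  print(x$improvement, digits = digits)
  cat("\n")
  cat("Proportional-odds LRT: statistic ",
      format(unname(x$lrt$statistic), digits = 4), ", df ",
      unname(x$lrt$parameter), ", p ",
      format(x$lrt$p.value, digits = 3), "\n", sep = "")
  cat("Pearson GOF: statistic ",
      format(unname(x$gof$statistic), digits = 4), ", df ",
      unname(x$gof$parameter), ", p ",
      format(x$gof$p.value, digits = 3), "\n\n", sep = "")
  print(x$comparison)
  invisible(x)
}

#' End-to-end selection pipeline on user or synthetic data
#'
#' Runs the full analysis chain on long-format data: enumerate the
#' candidate space over the given predictors, bootstrap the BIC scores,
#' apply the one-standard-error rule, refit the selected model on its own
#' largest complete-case sample, and compute improvement intervals when
#' the selected model permits them (i.e. contains only \code{phase} and
#' \code{init_rating}).
#'
#' @param data long-format data frame (see
#'   \code{\link{children_to_long}}).
#' @param predictors predictor vocabulary (default the ten study
#'   predictors).
#' @param B bootstrap replicates.
#' @param seed integer seed.
#' @param interactions logical; include single phase-interaction models.
#' @param resample,stratify passed to \code{\link{bootstrap_bic}}.
#' @return an object of class \code{"pipeline_report"}: list with the
#'   model space, bootstrap summary, indices and labels of the minimum-BIC
#'   and 1se choices, the refitted selected model, the subgroup BIC
#'   summary, and (when available) improvement intervals.
#' @export
run_pipeline <- function(data, predictors = study_predictors(), B = 200L,
                         seed = 1L, interactions = TRUE,
                         resample = "child", stratify = TRUE) {
  space <- model_space(predictors, interactions = interactions)
  boot <- bootstrap_bic(space, data, B = B, seed = seed,
                        resample = resample, stratify = stratify)
  i_1se <- select_1se(boot)
  i_min <- attr(i_1se, "min_index")
  spec <- space[[i_1se]]
  refit <- refit_complete_cases(spec, data)
  imp <- NULL
  if (setequal(spec$main, c("phase", "init_rating")) &&
      is.null(spec$interaction))
    imp <- bootstrap_improvement_ci(rating ~ phase + init_rating, data,
                                    B = B, seed = seed)
  structure(list(space = space, bootstrap = boot,
                 selected_index = as.integer(i_1se),
                 selected_label = boot$labels[i_1se],
                 min_bic_index = i_min,
                 min_bic_label = boot$labels[i_min],
                 fit = refit, improvement = imp,
                 subgroups = subgroup_bic_summary(boot),
                 meta = list(B = B, seed = seed, resample = resample,
                             stratify = stratify)),
            class = "pipeline_report")
}

#' @export
print.pipeline_report <- function(x, ...) {
  cat("==== Model-selection pipeline report ====\n")
  cat("space:", length(x$space), "models; B =", x$meta$B, "; seed =",
      x$meta$seed, "; resampling by", x$meta$resample,
      if (x$meta$stratify) "(stratified)", "\n")
  cat("minimum mean BIC:", x$min_bic_label, "\n")
  cat("1se selection:   ", x$selected_label, "\n\n")
  cat("Subgroup mean-BIC summary:\n")
  print(x$subgroups, row.names = FALSE)
  cat("\nSelected model refit on its largest complete-case sample:\n")
  print(x$fit)
  if (!is.null(x$improvement)) { cat("\n"); print(x$improvement) }
  invisible(x)
}
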