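#' Cohort-specific improvement indicator
#'
#' A child who started uncooperative (\code{init = 0}) has improved when
#' rated positive or definitely positive; a child who started cooperative
#' (\code{init = 1}) has improved only when rated definitely positive.
#'
#' @param init binary baseline cooperation indicator (0/1), recycled.
#' @param rating Frankl level(s) 1..4 or codes.
#' @return logical vector.
#' @examples
#' improved(0, 3)  # TRUE
#' improved(1, 3)  # FALSE
#' @export
improved <- function(init, rating) {
  r <- as_frankl(rating)
  stopifnot(all(init %in% 0:1))
  n <- max(length(init), length(r))
  init <- rep_len(init, n)
  r <- rep_len(r, n)
  ifelse(init == 0L, r >= 3L, r == 4L)
}

#' Model-based improvement probability
#'
#' The fitted probability of the cohort-specific improvement event:
#' \eqn{P(Y \ge 3)} for initially uncooperative children and
#' \eqn{P(Y = 4)} for initially cooperative children, at the given phase.
#' The fit must contain \code{phase} and \code{init_rating} and no other
#' predictors (otherwise the event probability is not determined by
#' \code{(init, phase)} alone).
#'
#' @param fit a \code{\link{pom}} fit on predictors \code{phase} and
#'   \code{init_rating}.
#' @param init binary indicator(s), recycled against \code{phase}.
#' @param phase phase number(s) in 1..3.
#' @return numeric vector of probabilities.
#' @examples
#' d <- counts_to_long(esba_phase_counts(), aggregate = TRUE)
#' fit <- pom(rating ~ phase + init_rating, d, weights = d$weight)
#' round(improvement_prob(fit, 0, 1:3), 4)
#' @export
improvement_prob <- function(fit, init, phase) {
  stopifnot(inherits(fit, "pom"))
  vars <- all.vars(stats::delete.response(fit$terms))
  if (!all(c("phase", "init_rating") %in% vars))
    stop("fit must contain both 'phase' and 'init_rating'")
  if (length(setdiff(vars, c("phase", "init_rating"))))
    stop("fit contains additional predictors (",
         paste(setdiff(vars, c("phase", "init_rating")), collapse = ", "),
         "); the improvement probability is not a function of (init, phase)")
  n <- max(length(init), length(phase))
  init <- rep_len(init, n); phase <- rep_len(phase, n)
  nd <- data.frame(phase = phase, init_rating = init)
  pr <- predict(fit, nd, type = "prob")
  ifelse(init == 0, pr[, 3] + pr[, 4], pr[, 4])
}

#' Percentile-bootstrap confidence intervals for improvement probabilities
#'
#' Refits the selected model on bootstrap copies of the data (children
#' resampled with replacement, stratified by baseline cohort by default)
#' and forms percentile intervals for the six improvement probabilities
#' (two cohorts by three phases). All six intervals come from one shared
#' set of bootstrap refits. Percentiles are empirical quantiles with linear
#' interpolation between order statistics (\code{quantile} type 7), so a
#' given seed reproduces the intervals bit-identically. Replicates with a
#' degenerate or non-converged refit are excluded and counted; more than
#' \code{B/2} invalid replicates is an error.
#'
#' @param formula model formula (must use \code{phase} and
#'   \code{init_rating} only), e.g. \code{rating ~ phase + init_rating}.
#' @param data long-format data with \code{child_id}, \code{phase},
#'   \code{init_rating}, \code{rating}.
#' @param B number of bootstrap replicates.
#' @param seed integer seed.
#' @param level confidence level.
#' @param resample \code{"child"} (default) or \code{"row"}.
#' @param stratify logical; resample within baseline cohort.
#' @return an object of class \code{"improvement_ci"}: a data frame with
#'   columns \code{init}, \code{phase}, \code{estimate}, \code{lower},
#'   \code{upper}; attributes \code{B}, \code{seed}, \code{level},
#'   \code{n_invalid}.
#' @export
bootstrap_improvement_ci <- function(formula = rating ~ phase + init_rating,
                                     data, B = 2000L, seed = 1L,
                                     level = 0.95,
                                     resample = c("child", "row"),
                                     stratify = TRUE) {
  resample <- match.arg(resample)
  vars <- all.vars(formula)
  if (!setequal(setdiff(vars, "rating"), c("phase", "init_rating")))
    stop("formula must use exactly the predictors 'phase' and 'init_rating'")
  keep <- stats::complete.cases(data[, setdiff(vars, "rating"),
                                     drop = FALSE]) & !is.na(data$rating)
  d <- data[keep, , drop = FALSE]
  fit0 <- pom(formula, d)
  point <- c(improvement_prob(fit0, 0, 1:3), improvement_prob(fit0, 1, 1:3))

  units <- if (resample == "child" && "child_id" %in% names(d))
    d$child_id else seq_len(nrow(d))
  uid <- unique(units)
  rows_of <- split(seq_len(nrow(d)), factor(units, levels = uid))
  strata <- if (stratify)
    vapply(rows_of, function(r) d$init_rating[r[1]], numeric(1))
  else rep(0, length(uid))
  idx_by_stratum <- split(seq_along(uid), strata)

  set.seed(seed)
  plan <- lapply(seq_len(B), function(b)
    unlist(lapply(idx_by_stratum, function(ix)
      sample(ix, length(ix), replace = TRUE)), use.names = FALSE))

  des <- .pom_design(formula, d)
  # pre-collapse into distinct (x, y) cells; replicates only re-weight
  key <- do.call(paste, c(as.data.frame(des$X), list(des$y, sep = "\r")))
  u <- !duplicated(key)
  cid <- match(key, key[u])
  Xc <- des$X[u, , drop = FALSE]; yc <- des$y[u]; ncell <- sum(u)
  start0 <- c(.theta_to_gamma(fit0$theta), fit0$beta)
  probs <- matrix(NA_real_, B, 6)
  for (b in seq_len(B)) {
    rows <- unlist(rows_of[plan[[b]]], use.names = FALSE)
    wcell <- tabulate(cid[rows], ncell)
    if (length(unique(yc[wcell > 0])) < 2L) next
    fit <- pom_fit_xy(Xc, yc, wcell, hessian = FALSE, collapse = FALSE,
                      start = start0)
    if (!fit$converged || fit$degenerate) next
    # event probabilities straight from the link
    th <- fit$theta
    bnames <- colnames(des$X)
    cf <- function(nm) { v <- fit$beta[match(nm, bnames)]
      if (is.na(v)) 0 else v }
    bph <- cf("phase"); bin <- cf("init_rating")
    bint <- cf("phase:init_rating") + cf("init_rating:phase")
    k <- 1L
    for (init in 0:1) for (ph in 1:3) {
      e <- bph * ph + bin * init + bint * ph * init
      probs[b, k] <- if (init == 0) 1 - plogis(th[2] - e) else
        1 - plogis(th[3] - e)
      k <- k + 1L
    }
  }
  valid <- stats::complete.cases(probs)
  if (sum(!valid) > B / 2)
    stop("more than B/2 bootstrap replicates were degenerate (",
         sum(!valid), " of ", B, ")")
  a <- (1 - level) / 2
  qs <- apply(probs[valid, , drop = FALSE], 2, stats::quantile,
              probs = c(a, 1 - a), type = 7)
  out <- data.frame(init = rep(0:1, each = 3), phase = rep(1:3, 2),
                    estimate = point, lower = qs[1, ], upper = qs[2, ])
  rownames(out) <- NULL
  structure(out, class = c("improvement_ci", "data.frame"),
            B = B, seed = seed, level = level, n_invalid = sum(!valid),
            resample = resample, stratify = stratify)
}

#' @export
print.improvement_ci <- function(x, digits = 4, ...) {
  cat("Improvement probabilities with ",
      format(100 * attr(x, "level")), "% percentile bootstrap CIs (B = ",
      attr(x, "B"), ", seed = ", attr(x, "seed"), ")\n", sep = "")
  y <- as.data.frame(x)
  y$cohort <- ifelse(y$init == 0, "uncooperative", "cooperative")
  y <- y[, c("cohort", "phase", "estimate", "lower", "upper")]
  y[, 3:5] <- round(y[, 3:5], digits)
  print(y, row.names = FALSE)
  if (attr(x, "n_invalid") > 0)
    cat("(", attr(x, "n_invalid"), " degenerate replicate(s) excluded )\n")
  invisible(x)
}

#' Observed versus model-predicted improvement percentages
#'
#' Side-by-side comparison, per cohort and phase, of the observed
#' improvement percentage from a count table and the percentage predicted
#' by the fitted model, optionally with bootstrap confidence bounds and a
#' flag for observed values falling outside their interval.
#'
#' @param fit a \code{\link{pom}} fit on \code{phase} and
#'   \code{init_rating}.
#' @param counts a \code{\link{phase_counts}} table.
#' @param cis optionally, a \code{\link{bootstrap_improvement_ci}} result.
#' @return an object of class \code{"improvement_comparison"}: data frame
#'   with observed and predicted percentages (and CI bounds and a
#'   \code{covered} flag when \code{cis} is given).
#' @export
improvement_comparison <- function(fit, counts, cis = NULL) {
  obs <- c(observed_improvement_pct(counts, "uncooperative"),
           observed_improvement_pct(counts, "cooperative"))
  pred <- 100 * c(improvement_prob(fit, 0, 1:3),
                  improvement_prob(fit, 1, 1:3))
  out <- data.frame(init = rep(0:1, each = 3), phase = rep(1:3, 2),
                    observed_pct = unname(obs), predicted_pct = pred)
  if (!is.null(cis)) {
    stopifnot(inherits(cis, "improvement_ci"))
    out$lower_pct <- 100 * cis$lower
    out$upper_pct <- 100 * cis$upper
    out$covered <- out$observed_pct >= out$lower_pct &
      out$observed_pct <= out$upper_pct
  }
  structure(out, class = c("improvement_comparison", "data.frame"))
}

#' @export
print.improvement_comparison <- function(x, digits = 2, ...) {
  cat("Observed vs model-predicted improvement percentages\n")
  y <- as.data.frame(x)
  y$cohort <- ifelse(y$init == 0, "uncooperative", "cooperative")
  num <- vapply(y, is.numeric, logical(1))
  y[num] <- lapply(y[num], round, digits)
  print(y[, c("cohort", setdiff(names(y), c("cohort", "init")))],
        row.names = FALSE)
  invisible(x)
}

#' @export
plot.improvement_comparison <- function(x, ...) {
  cols <- c("black", "red3")
  plot(NULL, xlim = c(0.8, 3.2), ylim = c(0, 100), xaxt = "n",
       xlab = "End of phase", ylab = "Children improved (%)", ...)
  graphics::axis(1, at = 1:3, labels = c("I", "II", "III"))
  for (i in 0:1) {
    d <- x[x$init == i, ]
    graphics::points(d$phase - 0.05, d$observed_pct, pch = 16,
                     col = cols[i + 1])
    graphics::points(d$phase + 0.05, d$predicted_pct, pch = 1,
                     col = cols[i + 1])
    graphics::lines(d$phase + 0.05, d$predicted_pct, lty = 2,
                    col = cols[i + 1])
    if (!is.null(d$lower_pct))
      graphics::segments(d$phase + 0.05, d$lower_pct, d$phase + 0.05,
                         d$upper_pct, col = cols[i + 1])
  }
  graphics::legend("topleft", bty = "n",
                   legend = c("observed (uncooperative)",
                              "predicted (uncooperative)",
                              "observed (cooperative)",
                              "predicted (cooperative)"),
                   pch = c(16, 1, 16, 1), col = cols[c(1, 1, 2, 2)])
  invisible(x)
}
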