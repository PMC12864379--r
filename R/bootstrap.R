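# Shared design for scanning a model space: one full model matrix, with
# per-spec column subsets; interaction columns are phase * dummy columns,
# identical to what model.matrix would produce for phase:x with both main
# effects present.
.space_design <- function(space, data, weights = NULL) {
  vocab <- attr(space, "vocabulary")
  keep <- stats::complete.cases(data[, vocab, drop = FALSE]) &
    !is.na(data$rating)
  d <- data[keep, , drop = FALSE]
  w <- if (is.null(weights)) rep(1, nrow(d)) else weights[keep]
  f <- stats::as.formula(paste("rating ~", paste(vocab, collapse = " + ")),
                         env = globalenv())
  tt <- stats::terms(f)
  mf <- stats::model.frame(tt, d)
  y <- stats::model.response(mf)
  y <- if (is.factor(y)) as.integer(y) else as_frankl(y)
  Xfull <- stats::model.matrix(tt, mf)
  ok <- colnames(Xfull) != "(Intercept)"
  X <- Xfull[, ok, drop = FALSE]
  asg <- attr(Xfull, "assign")[ok]
  tl <- attr(tt, "term.labels")
  cols_of <- split(seq_len(ncol(X)), factor(tl[asg], levels = tl))
  specs_cols <- lapply(space, function(s) {
    list(main = unlist(cols_of[s$main], use.names = FALSE),
         inter = if (!is.null(s$interaction))
           cols_of[[s$interaction]] else integer(0))
  })
  phase_col <- if ("phase" %in% vocab) X[, cols_of[["phase"]][1]] else NULL
  list(X = X, y = y, w = w, cols = specs_cols,
       phase = phase_col, keep = keep, data = d,
       child_id = if ("child_id" %in% names(d)) d$child_id else
         seq_len(nrow(d)))
}

# design matrix of one spec given row subset (integer index, possibly with
# repeats from resampling)
.spec_matrix <- function(sd, i_spec, rows) {
  cc <- sd$cols[[i_spec]]
  X <- sd$X[rows, cc$main, drop = FALSE]
  if (length(cc$inter)) {
    XI <- sd$X[rows, cc$inter, drop = FALSE] * sd$phase[rows]
    colnames(XI) <- paste0("phase:", colnames(sd$X)[cc$inter])
    X <- cbind(X, XI)
  }
  X
}

#' BIC of every candidate model on one dataset
#'
#' Fits each specification of a model space to the complete-case sample for
#' the full vocabulary (so all BICs are comparable) and returns the BIC
#' scores.
#'
#' @param space a \code{\link{model_space}}.
#' @param data long-format data with a \code{rating} column.
#' @param weights optional case weights.
#' @return an object of class \code{"bic_scan"}: list with \code{bic},
#'   \code{n_params}, \code{loglik}, \code{labels}, \code{n_obs}.
#' @examples
#' d <- counts_to_long(esba_phase_counts(), aggregate = TRUE)
#' sp <- model_space(c("phase", "init_rating"))
#' bic_scan(sp, d, weights = d$weight)$bic
#' @export
bic_scan <- function(space, data, weights = NULL) {
  sd <- .space_design(space, data, weights)
  rows <- seq_along(sd$y)
  M <- length(space)
  bic <- ll <- np <- rep(NA_real_, M)
  n <- sum(sd$w)
  for (m in seq_len(M)) {
    X <- .spec_matrix(sd, m, rows)
    fit <- pom_fit_xy(X, sd$y, sd$w, hessian = FALSE)
    if (fit$converged) {
      ll[m] <- fit$loglik
      np[m] <- fit$n_params
      bic[m] <- -2 * fit$loglik + fit$n_params * log(n)
    }
  }
  structure(list(bic = bic, n_params = np, loglik = ll,
                 labels = vapply(space, spec_label, character(1)),
                 n_obs = n, space = space),
            class = "bic_scan")
}

#' Bootstrap distribution of BIC scores over a model space
#'
#' Implements the resampling stage of the one-standard-error BIC rule:
#' bootstrap copies of the dataset are drawn, every candidate model is
#' refitted on each copy, and per-model means and standard deviations of
#' the BIC scores are recorded. Resampling is by child (all phase rows of a
#' child move together), stratified by baseline cohort so that both cohorts
#' keep their original sizes in every replicate; row-level and unstratified
#' resampling are available for sensitivity analysis. All models are fitted
#' on the complete-case sample for the full vocabulary, as in the selection
#' stage of the study design.
#'
#' Replicates in which a model is degenerate (an unobserved response
#' category, a constant design column, or no convergence) are excluded from
#' that model's summary and counted; a model invalid in more than half the
#' replicates is marked invalid (\code{NA} mean).
#'
#' @param space a \code{\link{model_space}}.
#' @param data long-format data (must contain \code{child_id} for
#'   child-level resampling and \code{init_rating} for stratification).
#' @param B number of bootstrap replicates.
#' @param seed integer seed; the resampling plan is drawn up front, so
#'   results are bit-reproducible given \code{(seed, B, space, data)}.
#' @param resample \code{"child"} or \code{"row"}.
#' @param stratify logical; resample within baseline cohort.
#' @return an object of class \code{"bootstrap_bic"}: list with
#'   \code{mean}, \code{sd}, \code{n_params}, \code{n_invalid},
#'   \code{bic} (B x M matrix), \code{labels}, \code{B}, \code{seed}.
#' @seealso \code{\link{select_1se}}, \code{\link{select_min_bic}}
#' @export
bootstrap_bic <- function(space, data, B = 2000L, seed = 1L,
                          resample = c("child", "row"), stratify = TRUE) {
  resample <- match.arg(resample)
  sd_ <- .space_design(space, data)
  M <- length(space)
  n_params <- vapply(seq_len(M), function(m)
    3L + length(sd_$cols[[m]]$main) + length(sd_$cols[[m]]$inter), integer(1))
  units <- if (resample == "child") sd_$child_id else seq_along(sd_$y)
  uid <- unique(units)
  rows_of <- split(seq_along(sd_$y), factor(units, levels = uid))
  strata <- if (stratify && "init_rating" %in% names(sd_$data)) {
    vapply(rows_of, function(r) sd_$data$init_rating[r[1]], numeric(1))
  } else rep(0, length(uid))
  idx_by_stratum <- split(seq_along(uid), strata)

  set.seed(seed)
  plan <- lapply(seq_len(B), function(b)
    unlist(lapply(idx_by_stratum, function(ix)
      sample(ix, length(ix), replace = TRUE)), use.names = FALSE))

  # Pre-collapse each spec's design into its distinct (x, y) cells once;
  # a replicate then only re-weights cells, which makes refits cheap.
  all_rows <- seq_along(sd_$y)
  unit_w <- all(sd_$w == 1)
  cells <- lapply(seq_len(M), function(m) {
    Xm <- .spec_matrix(sd_, m, all_rows)
    key <- do.call(paste, c(as.data.frame(Xm), list(sd_$y, sep = "\r")))
    u <- !duplicated(key)
    id <- match(key, key[u])
    f0 <- pom_fit_xy(Xm[u, , drop = FALSE], sd_$y[u],
                     as.vector(rowsum(sd_$w, id)), hessian = FALSE,
                     collapse = FALSE)
    start <- if (f0$converged)
      c(.theta_to_gamma(f0$theta), f0$beta) else NULL
    list(X = Xm[u, , drop = FALSE], y = sd_$y[u], id = id, ncell = sum(u),
         start = start)
  })

  bic <- matrix(NA_real_, B, M)
  for (b in seq_len(B)) {
    rows <- unlist(rows_of[plan[[b]]], use.names = FALSE)
    y <- sd_$y[rows]
    wts <- sd_$w[rows]
    n <- sum(wts)
    cat_ok <- all(tabulate(y, 4L) > 0L)
    rng <- apply(sd_$X[rows, , drop = FALSE], 2, range)
    const_col <- rng[1, ] == rng[2, ]
    for (m in seq_len(M)) {
      cc <- sd_$cols[[m]]
      if (!cat_ok || any(const_col[c(cc$main, cc$inter)])) next
      cl <- cells[[m]]
      wcell <- if (unit_w) tabulate(cl$id[rows], cl$ncell) else {
        wc <- numeric(cl$ncell)
        t <- rowsum(wts, cl$id[rows])
        wc[as.integer(rownames(t))] <- t
        wc
      }
      fit <- pom_fit_xy(cl$X, cl$y, wcell, hessian = FALSE,
                        collapse = FALSE, start = cl$start)
      if (fit$converged && !fit$degenerate)
        bic[b, m] <- -2 * fit$loglik + n_params[m] * log(n)
    }
  }
  n_invalid <- colSums(is.na(bic))
  mu <- colMeans(bic, na.rm = TRUE)
  sdev <- apply(bic, 2, stats::sd, na.rm = TRUE)
  bad <- n_invalid > B / 2
  if (any(bad)) {
    warning(sum(bad), " model(s) invalid in more than B/2 replicates; ",
            "excluded from selection")
    mu[bad] <- NA_real_
  }
  mu[!is.finite(mu)] <- NA_real_
  structure(list(mean = mu, sd = sdev, n_params = n_params,
                 n_invalid = n_invalid, bic = bic,
                 labels = vapply(space, spec_label, character(1)),
                 B = B, seed = seed, resample = resample,
                 stratify = stratify, space = space),
            class = "bootstrap_bic")
}

#' @export
print.bootstrap_bic <- function(x, ...) {
  cat("Bootstrap BIC summary: ", length(x$mean), " models, B = ", x$B,
      ", seed = ", x$seed, ", resampling by ", x$resample,
      if (x$stratify) " (stratified by cohort)", "\n", sep = "")
  i <- select_min_bic(x$mean, x$n_params)
  cat("min mean BIC: ", format(x$mean[i], digits = 6), " [", x$labels[i],
      "], sd ", format(x$sd[i], digits = 4), "\n", sep = "")
  j <- select_1se(x)
  cat("1se choice:   ", format(x$mean[j], digits = 6), " [", x$labels[j],
      "]\n", sep = "")
  invisible(x)
}

#' Subgroup BIC summary
#'
#' Per-subgroup range of (mean) BIC scores over the five-way partition of
#' the model space by phase / baseline-indicator membership, the numeric
#' analogue of the study's side-by-side boxplot.
#'
#' @param scan a \code{\link{bic_scan}} or \code{\link{bootstrap_bic}}
#'   result.
#' @return data frame with one row per subgroup: size, min, median, max.
#' @export
subgroup_bic_summary <- function(scan) {
  bic <- if (inherits(scan, "bootstrap_bic")) scan$mean else scan$bic
  part <- partition_phase_init(scan$space)
  out <- do.call(rbind, lapply(names(part), function(g) {
    v <- bic[part[[g]]]
    data.frame(subgroup = g, n_models = length(part[[g]]),
               min = suppressWarnings(min(v, na.rm = TRUE)),
               median = stats::median(v, na.rm = TRUE),
               max = suppressWarnings(max(v, na.rm = TRUE)))
  }))
  rownames(out) <- NULL
  out
}
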