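#' The ten study predictors
#'
#' Names, in canonical order, of the ten explanatory variables used in the
#' modelling: the phase of the programme, the baseline cooperation
#' indicator, and eight baseline covariates. The names match the columns
#' produced by \code{\link{children_to_long}} on records from
#' \code{\link{simulate_cohort}}.
#'
#' @return character vector of length 10.
#' @export
study_predictors <- function() {
  c("phase", "init_rating", "age", "gender", "natural_birth", "medication",
    "prev_anesthesia", "dmft", "gingival", "plaque")
}

#' Enumerate the candidate model space
#'
#' Builds every candidate specification over a predictor vocabulary: all
#' \eqn{2^p} subsets of main effects, plus, for every subset containing
#' \code{phase} and at least one other predictor \eqn{X}, one additional
#' specification per choice of a single \code{phase:X} interaction. For the
#' ten study predictors this gives \eqn{2^{10} + 9 \cdot 2^8 = 3328}
#' candidates. Ordering is deterministic: main-effect subsets in binary
#' order of the vocabulary, then interaction models grouped by subset.
#'
#' @param vocabulary character vector of predictor names; interactions are
#'   generated only when it contains \code{"phase"}.
#' @param interactions logical; set \code{FALSE} for the plain power set.
#' @return an object of class \code{"model_space"}: a list of
#'   specifications, each a list with elements \code{main} (character) and
#'   \code{interaction} (\code{NULL} or the name interacting with phase).
#' @examples
#' length(model_space(study_predictors()))  # 3328
#' @export
model_space <- function(vocabulary = study_predictors(),
                        interactions = TRUE) {
  stopifnot(is.character(vocabulary), !anyDuplicated(vocabulary))
  p <- length(vocabulary)
  if (interactions && !("phase" %in% vocabulary)) {
    warning("vocabulary has no 'phase': returning the plain power set")
    interactions <- FALSE
  }
  specs <- vector("list", 2^p)
  for (i in seq_len(2^p)) {
    main <- vocabulary[bitwAnd(i - 1L, bitwShiftL(1L, seq_len(p) - 1L)) > 0L]
    specs[[i]] <- list(main = main, interaction = NULL)
  }
  if (interactions) {
    extra <- list()
    for (s in specs) {
      if (!("phase" %in% s$main)) next
      for (x in setdiff(s$main, "phase"))
        extra[[length(extra) + 1L]] <- list(main = s$main, interaction = x)
    }
    specs <- c(specs, extra)
  }
  structure(specs, class = "model_space", vocabulary = vocabulary)
}

#' @export
print.model_space <- function(x, ...) {
  cat("Model space over {", paste(attr(x, "vocabulary"), collapse = ", "),
      "}\n", sep = "")
  n_int <- sum(vapply(x, function(s) !is.null(s$interaction), logical(1)))
  cat(length(x), "candidate models (", length(x) - n_int, "main-effect,",
      n_int, "with a phase interaction )\n")
  invisible(x)
}

#' Model formula of a specification
#'
#' @param spec one element of a \code{\link{model_space}}.
#' @param response name of the response column.
#' @return a formula.
#' @export
spec_formula <- function(spec, response = "rating") {
  rhs <- c(spec$main,
           if (!is.null(spec$interaction))
             paste0("phase:", spec$interaction))
  if (!length(rhs)) rhs <- "1"
  stats::as.formula(paste(response, "~", paste(rhs, collapse = " + ")),
                    env = globalenv())
}

# short human-readable label of a spec
spec_label <- function(spec) {
  lab <- if (length(spec$main)) paste(spec$main, collapse = "+") else "1"
  if (!is.null(spec$interaction))
    lab <- paste0(lab, "+phase:", spec$interaction)
  lab
}

#' Partition a model space by phase / baseline-indicator membership
#'
#' Splits the candidate models into the five disjoint subgroups used in the
#' study's BIC comparison: (i) models containing neither \code{phase} nor
#' \code{init_rating}; (ii) \code{phase} only; (iii) \code{init_rating}
#' only; (iv) both, with no interaction; (v) both, plus the single
#' phase-by-covariate interaction (any interacting covariate; models with a
#' phase interaction but without \code{init_rating} fall in subgroup (ii)).
#'
#' @param space a \code{\link{model_space}}.
#' @return named list of five integer index vectors, with an attribute
#'   \code{sizes}.
#' @examples
#' lengths(partition_phase_init(model_space(study_predictors())))
#' @export
partition_phase_init <- function(space) {
  stopifnot(inherits(space, "model_space"))
  has_phase <- vapply(space, function(s) "phase" %in% s$main, logical(1))
  has_init <- vapply(space, function(s) "init_rating" %in% s$main, logical(1))
  has_int <- vapply(space, function(s) !is.null(s$interaction), logical(1))
  out <- list(
    neither = which(!has_phase & !has_init),
    phase_only = which(has_phase & !has_init),
    init_only = which(!has_phase & has_init),
    both_no_interaction = which(has_phase & has_init & !has_int),
    both_with_interaction = which(has_phase & has_init & has_int))
  attr(out, "sizes") <- lengths(out)
  out
}

# number of free parameters of a spec fitted to `data` (thresholds + slope
# columns after dummy expansion)
spec_n_params <- function(spec, data, K = 4L) {
  tt <- stats::delete.response(stats::terms(spec_formula(spec)))
  vars <- unique(c(spec$main, spec$interaction))
  d <- if (length(vars))
    data[stats::complete.cases(data[, vars, drop = FALSE]), , drop = FALSE]
  else data
  X <- stats::model.matrix(tt, d)
  (K - 1L) + sum(colnames(X) != "(Intercept)")
}

#' Fit a specification on its largest complete-case sample
#'
#' Restricts the data to rows complete on the specification's own
#' predictors only (so sparser models keep more children), then fits the
#' proportional-odds model. This is the refitting convention used after
#' model selection: each model is estimated on the largest sample with
#' complete information about its own regressors.
#'
#' @param spec a model specification (element of a
#'   \code{\link{model_space}}), or a character vector of main effects.
#' @param data long-format data with a \code{rating} column.
#' @param weights optional case weights.
#' @return a \code{\link{pom}} fit; its \code{n_children} attribute gives
#'   the number of distinct children retained when a \code{child_id} column
#'   is present.
#' @export
refit_complete_cases <- function(spec, data, weights = NULL) {
  if (is.character(spec)) spec <- list(main = spec, interaction = NULL)
  vars <- unique(c(spec$main, spec$interaction))
  keep <- if (length(vars))
    stats::complete.cases(data[, vars, drop = FALSE]) else
      rep(TRUE, nrow(data))
  d <- data[keep, , drop = FALSE]
  w <- if (!is.null(weights)) weights[keep]
  fit <- pom(spec_formula(spec), data = d, weights = w)
  fit$spec <- spec
  if ("child_id" %in% names(d))
    attr(fit, "n_children") <- length(unique(d$child_id))
  fit
}

#' Minimum-BIC model choice
#'
#' Returns the index of the model with smallest (mean) BIC. Ties are broken
#' in favour of fewer free parameters, then by canonical order.
#'
#' @param bic numeric vector of BIC scores (or bootstrap means), possibly
#'   with \code{NA} for invalid models.
#' @param n_params optional parameter counts used for tie-breaking.
#' @return integer index of the selected model.
#' @export
select_min_bic <- function(bic, n_params = NULL) {
  ok <- which(is.finite(bic))
  if (!length(ok)) stop("no valid model to select from")
  best <- min(bic[ok])
  cand <- ok[bic[ok] <= best + 1e-9]
  if (length(cand) > 1L && !is.null(n_params))
    cand <- cand[n_params[cand] == min(n_params[cand])]
  cand[1L]
}

#' One-standard-error model choice
#'
#' Implements the bootstrap BIC one-standard-error rule: let \eqn{m^*} be
#' the model with minimum bootstrap-mean BIC and \eqn{se} the standard
#' deviation of its bootstrap BIC scores; among all models whose mean BIC
#' lies within \eqn{(\overline{BIC} - se,\ \overline{BIC} + se)}, return
#' the most parsimonious one (fewest free parameters; ties broken by lower
#' mean BIC, then canonical order).
#'
#' @param summary a \code{\link{bootstrap_bic}} result, or a list with
#'   elements \code{mean}, \code{sd} and \code{n_params}.
#' @return integer index of the selected model, with attributes
#'   \code{min_index}, \code{interval}.
#' @export
select_1se <- function(summary) {
  m <- summary$mean; s <- summary$sd; np <- summary$n_params
  i_min <- select_min_bic(m, np)
  se <- s[i_min]
  lo <- m[i_min] - se; hi <- m[i_min] + se
  cand <- which(is.finite(m) & m > lo & m < hi)
  if (!length(cand)) cand <- i_min
  cand <- cand[np[cand] == min(np[cand])]
  if (length(cand) > 1L) cand <- cand[which.min(m[cand])]
  structure(cand[1L], min_index = i_min, interval = c(lower = lo, upper = hi))
}
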