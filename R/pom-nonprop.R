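#' Cumulative logit model without proportional odds
#'
#' Joint maximum-likelihood fit of the unconstrained cumulative logit model
#' in which every cumulative logit has its own slope vector:
#' \deqn{\mathrm{logit}\, P(Y \le j \mid x) = \theta_j - x'\beta_j.}
#' This is the alternative hypothesis of the proportional-odds likelihood
#' ratio test (\code{\link{lrt_prop_odds}}). Monotonicity of the implied
#' cumulative probabilities across \eqn{j} is not enforced (the alternative
#' is unconstrained); parameter values that would give a non-positive
#' category probability at an observed covariate pattern are simply
#' infeasible for the likelihood and are avoided by the line search. If the
#' fitted cumulative probabilities cross anywhere on the observed design the
#' result is flagged (\code{monotone = FALSE}) but still returned.
#'
#' @inheritParams pom
#' @return an object of class \code{"pom_nonprop"}: per-logit intercepts
#'   \code{theta} (length 3), slope matrix \code{beta} (\code{p} x 3, one
#'   column per cumulative logit), \code{loglik}, \code{n_obs},
#'   \code{n_params} \eqn{= 3(1 + p)}, \code{converged}, \code{monotone}.
#' @examples
#' d <- counts_to_long(esba_phase_counts(), aggregate = TRUE)
#' np <- pom_nonprop(rating ~ phase + init_rating, d, weights = d$weight)
#' logLik(np)
#' @export
pom_nonprop <- function(formula, data, weights = NULL, start = NULL,
                        tol = 1e-8, max_iter = 1000L) {
  cl <- match.call()
  des <- .pom_design(formula, data, weights)
  X <- des$X; y <- des$y; w <- des$w
  K <- 4L; p <- ncol(X)
  # collapse duplicated rows
  key <- do.call(paste, c(as.data.frame(X), list(y, sep = "\r")))
  if (anyDuplicated(key)) {
    first <- !duplicated(key)
    w <- as.vector(rowsum(w, key))[match(key[first], sort(unique(key)))]
    X <- X[first, , drop = FALSE]; y <- y[first]
  }
  n_total <- sum(des$w)

  eta_j <- function(B, j) if (p) drop(X %*% B[, j]) else numeric(nrow(X))
  nll <- function(par) {
    th <- par[1:(K - 1)]
    B <- matrix(par[-(1:(K - 1))], nrow = p)
    cum <- vapply(1:(K - 1),
                  function(j) plogis(th[j] - eta_j(B, j)),
                  numeric(nrow(X)))
    cum <- matrix(cum, nrow = nrow(X))
    pr <- cbind(cum[, 1], cum[, -1, drop = FALSE] -
                  cum[, -(K - 1), drop = FALSE], 1 - cum[, K - 1])
    pi <- pr[cbind(seq_along(y), y)]
    if (any(pi <= 0) || any(!is.finite(pi))) return(1e10)
    -sum(w * log(pi))
  }
  grad <- function(par) {
    th <- par[1:(K - 1)]
    B <- matrix(par[-(1:(K - 1))], nrow = p)
    g_th <- numeric(K - 1)
    g_B <- matrix(0, p, K - 1)
    cum <- vapply(1:(K - 1),
                  function(j) plogis(th[j] - eta_j(B, j)),
                  numeric(nrow(X)))
    cum <- matrix(cum, nrow = nrow(X))
    pr <- cbind(cum[, 1], cum[, -1, drop = FALSE] -
                  cum[, -(K - 1), drop = FALSE], 1 - cum[, K - 1])
    pi <- pr[cbind(seq_along(y), y)]
    if (any(pi <= 0) || any(!is.finite(pi))) return(rep(0, length(par)))
    for (j in 1:(K - 1)) {
      f <- cum[, j] * (1 - cum[, j])
      # d pi / d th_j: +f for y == j, -f for y == j + 1
      s <- (y == j) - (y == j + 1L)
      g_th[j] <- -sum(w * s * f / pi)
      if (p) g_B[, j] <- drop(crossprod(X, w * s * f / pi))
    }
    c(g_th, as.vector(g_B))
  }

  if (is.null(start)) {
    pf <- pom_fit_xy(X, y, w, K = K, hessian = FALSE)
    start <- c(pf$theta, rep(pf$beta, K - 1))
  }
  opt <- optim(start, nll, grad, method = "BFGS",
               control = list(maxit = max_iter, reltol = 1e-14))
  # alternate polish rounds; the feasible region can make BFGS stall
  for (i in 1:2) {
    o2 <- optim(opt$par, nll, method = "Nelder-Mead",
                control = list(maxit = 5000, reltol = 1e-14))
    if (o2$value < opt$value) opt <- o2
    o3 <- optim(opt$par, nll, grad, method = "BFGS",
                control = list(maxit = max_iter, reltol = 1e-16))
    if (o3$value < opt$value) opt <- o3
  }
  th <- opt$par[1:(K - 1)]
  B <- matrix(opt$par[-(1:(K - 1))], nrow = p, ncol = K - 1)
  dimnames(B) <- list(colnames(X), paste0("logit", 1:(K - 1)))
  cum <- vapply(1:(K - 1),
                function(j) plogis(th[j] - eta_j(B, j)),
                numeric(nrow(X)))
  cum <- matrix(cum, nrow = nrow(X))
  monotone <- all(diff(t(cum)) >= -1e-10)
  g <- grad(opt$par)
  structure(list(theta = th, beta = B, loglik = -opt$value,
                 n_obs = n_total, n_params = (K - 1) * (1 + p),
                 converged = max(abs(g)) < max(tol, 1e-4, 1e-6 * n_total) &&
                   opt$value < 1e9,
                 monotone = monotone, K = K, call = cl, formula = formula),
            class = "pom_nonprop")
}

#' @export
print.pom_nonprop <- function(x, digits = 4, ...) {
  cat("Cumulative logit model without proportional odds\n")
  cat("logit P(Y <= j | x) = theta_j - x'beta_j\n\n")
  cat("Per-logit intercepts:\n")
  print(round(setNames(x$theta, paste0(1:(x$K - 1), "|", 2:x$K)), digits))
  if (length(x$beta)) {
    cat("\nPer-logit slopes (columns = cumulative logits):\n")
    print(round(x$beta, digits))
  }
  cat("\nlog-likelihood:", format(x$loglik, digits = 7),
      " params:", x$n_params, " n:", x$n_obs, "\n")
  if (!x$monotone)
    cat("NOTE: fitted cumulative probabilities cross at some observed x\n")
  invisible(x)
}

#' @export
logLik.pom_nonprop <- function(object, ...) {
  structure(object$loglik, df = object$n_params, nobs = object$n_obs,
            class = "logLik")
}

#' Likelihood ratio test of the proportional-odds assumption
#'
#' Compares a proportional-odds fit with the unconstrained per-logit-slope
#' model on the same data: statistic \eqn{2(\ell_1 - \ell_0)}, degrees of
#' freedom equal to the difference in parameter counts (\eqn{(K - 2) p} for
#' \eqn{p} slope columns and \eqn{K} categories), p-value from the
#' chi-square distribution. When only the proportional fit is supplied the
#' unconstrained model is fitted internally on the same design.
#'
#' @param prop a \code{\link{pom}} fit.
#' @param nonprop optionally, a matching \code{\link{pom_nonprop}} fit.
#' @param data,weights data used to refit the unconstrained model when
#'   \code{nonprop} is missing; defaults to re-evaluating the call of
#'   \code{prop}.
#' @return an object of class \code{"htest"}.
#' @examples
#' d <- counts_to_long(esba_phase_counts(), aggregate = TRUE)
#' fit <- pom(rating ~ phase + init_rating, d, weights = d$weight)
#' lrt_prop_odds(fit)
#' @export
lrt_prop_odds <- function(prop, nonprop = NULL, data = NULL, weights = NULL) {
  stopifnot(inherits(prop, "pom"))
  if (is.null(nonprop)) {
    if (is.null(data)) {
      data <- eval(prop$call$data, environment(prop$formula))
      weights <- eval(prop$call$weights, data, environment(prop$formula))
    }
    nonprop <- pom_nonprop(prop$formula, data, weights)
  }
  stopifnot(inherits(nonprop, "pom_nonprop"))
  if (nonprop$n_obs != prop$n_obs)
    stop("the two fits use different numbers of observations (",
         prop$n_obs, " vs ", nonprop$n_obs, ")")
  stat <- 2 * (nonprop$loglik - prop$loglik)
  df <- nonprop$n_params - prop$n_params
  if (stat < 0 && stat > -1e-6) stat <- 0  # numerically tied optima
  structure(list(statistic = c(`LR chi-square` = stat),
                 parameter = c(df = df),
                 p.value = pchisq(stat, df, lower.tail = FALSE),
                 method = paste("Likelihood ratio test of proportional odds",
                                "(common slopes vs per-logit slopes)"),
                 data.name = deparse(prop$formula)),
            class = "htest")
}

#' Pearson goodness-of-fit test over covariate patterns
#'
#' Groups the fitting data into the distinct covariate patterns of the
#' model design, crosses them with the four response categories, and
#' computes \eqn{X^2 = \sum (O - E)^2 / E}. Degrees of freedom are
#' \code{patterns * (K - 1) - n_params}. Cells with expected counts below
#' \code{floor} trigger a warning (the chi-square approximation is then
#' doubtful) but are not merged.
#'
#' @param object a \code{\link{pom}} fit.
#' @param data,weights fitting data; default re-evaluates the fit's call.
#' @param floor minimum expected count below which a warning is emitted.
#' @return an object of class \code{"htest"}.
#' @export
pearson_gof <- function(object, data = NULL, weights = NULL, floor = 1) {
  stopifnot(inherits(object, "pom"))
  if (is.null(data)) {
    data <- eval(object$call$data, environment(object$formula))
    weights <- eval(object$call$weights, data, environment(object$formula))
  }
  g <- .pom_cells(object, data, weights)
  low <- g$expected < floor
  if (any(low))
    warning(sum(low), " cell(s) have expected count below ", floor,
            "; chi-square approximation may be poor")
  stat <- sum((g$observed - g$expected)^2 / g$expected)
  npat <- length(unique(g$pattern))
  df <- npat * (object$K - 1) - object$n_params
  structure(list(statistic = c(`X-squared` = stat),
                 parameter = c(df = df),
                 p.value = pchisq(stat, df, lower.tail = FALSE),
                 method = paste("Pearson goodness-of-fit test",
                                "(covariate patterns x categories)"),
                 data.name = deparse(object$formula)),
            class = "htest")
}
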