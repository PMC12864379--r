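# Core maximum-likelihood machinery for cumulative logit models.
#
# Parameterization: logit P(Y <= j | x) = theta_j - x'beta (latent-variable
# sign convention: positive beta pushes mass toward higher categories).
# Thresholds are optimized as gamma = (theta_1, log(theta_2 - theta_1),
# log(theta_3 - theta_2)) so ordering holds by construction.

# Stable P(a < Z <= b) for logistic Z: plogis(a) - plogis(b) with b <= a,
# computed as plogis(a) * plogis(-b) * (-expm1(b - a)); exact at +/-Inf.
.logis_band <- function(a, b) {
  plogis(a) * plogis(-b) * (-expm1(b - a))
}

.gamma_to_theta <- function(gamma) cumsum(c(gamma[1], exp(gamma[-1])))

.theta_to_gamma <- function(theta) c(theta[1], log(diff(theta)))

# Negative log-likelihood and analytic gradient in the (gamma, beta)
# parameterization. X: n x p model matrix (no intercept), y: integer 1..K,
# w: case weights.
.pom_nll <- function(par, X, y, w, K) {
  p <- ncol(X)
  theta <- .gamma_to_theta(par[seq_len(K - 1)])
  beta <- par[K - 1 + seq_len(p)]
  eta <- if (p) drop(X %*% beta) else numeric(nrow(X))
  thetaX <- c(-Inf, theta, Inf)
  a <- thetaX[y + 1L] - eta   # upper cut
  b <- thetaX[y] - eta        # lower cut
  pr <- .logis_band(a, b)
  if (any(pr <= 0) || any(!is.finite(pr))) return(1e10)
  -sum(w * log(pr))
}

.pom_grad <- function(par, X, y, w, K) {
  p <- ncol(X)
  gamma <- par[seq_len(K - 1)]
  theta <- .gamma_to_theta(gamma)
  beta <- par[K - 1 + seq_len(p)]
  eta <- if (p) drop(X %*% beta) else numeric(nrow(X))
  thetaX <- c(-Inf, theta, Inf)
  a <- thetaX[y + 1L] - eta
  b <- thetaX[y] - eta
  pr <- .logis_band(a, b)
  if (any(pr <= 0) || any(!is.finite(pr))) return(rep(0, length(par)))
  fa <- plogis(a) * plogis(-a)  # logistic density, 0 at +/-Inf
  fb <- plogis(b) * plogis(-b)
  # d(-log pr)/d theta_j: -fa/pr if y == j, +fb/pr if y == j + 1
  gtheta <- numeric(K - 1)
  ratio_a <- w * fa / pr
  ratio_b <- w * fb / pr
  for (j in seq_len(K - 1)) {
    gtheta[j] <- -sum(ratio_a[y == j]) + sum(ratio_b[y == j + 1L])
  }
  # chain rule to gamma: dtheta_j/dgamma_1 = 1; dtheta_j/dgamma_m =
  # exp(gamma_m) for m <= j (m >= 2)
  ggamma <- numeric(K - 1)
  ggamma[1] <- sum(gtheta)
  if (K > 2)
    for (m in 2:(K - 1)) ggamma[m] <- exp(gamma[m]) * sum(gtheta[m:(K - 1)])
  # d(-log pr)/d beta = (fa - fb)/pr * x  (since d a/d beta = d b/d beta = -x)
  gbeta <- if (p) drop(crossprod(X, ratio_a - ratio_b)) else numeric(0)
  c(ggamma, gbeta)
}

# NLL in the direct (theta, beta) parameterization, used for the Hessian.
.pom_nll_direct <- function(par, X, y, w, K) {
  p <- ncol(X)
  theta <- par[seq_len(K - 1)]
  if (is.unsorted(theta, strictly = TRUE)) return(1e10)
  beta <- par[K - 1 + seq_len(p)]
  eta <- if (p) drop(X %*% beta) else numeric(nrow(X))
  thetaX <- c(-Inf, theta, Inf)
  pr <- .logis_band(thetaX[y + 1L] - eta, thetaX[y] - eta)
  if (any(pr <= 0) || any(!is.finite(pr))) return(1e10)
  -sum(w * log(pr))
}

# Low-level fit on a prepared design. Returns a bare list; the formula
# interface dresses it up. Collapses duplicated design rows into weights
# first (likelihood is identical), which makes bootstrap refits cheap.
pom_fit_xy <- function(X, y, w = rep(1, length(y)), K = 4L, start = NULL,
                       tol = 1e-8, max_iter = 500L, hessian = TRUE,
                       collapse = TRUE) {
  X <- as.matrix(X)
  keep <- w > 0
  X <- X[keep, , drop = FALSE]; y <- y[keep]; w <- w[keep]
  n_total <- sum(w)
  if (collapse) {
    # collapse identical (x, y) rows
    key <- do.call(paste, c(as.data.frame(X), list(y, sep = "\r")))
    if (anyDuplicated(key)) {
      first <- !duplicated(key)
      w <- as.vector(rowsum(w, key))[match(key[first], sort(unique(key)))]
      X <- X[first, , drop = FALSE]; y <- y[first]
    }
  }
  p <- ncol(X)
  if (is.null(start)) {
    cw <- cumsum(rowsum(c(w, rep(0, K)), factor(c(y, 1:K), levels = 1:K))[, 1])
    prop <- pmin(pmax(cw[-K] / n_total, 1e-3), 1 - 1e-3)
    theta0 <- qlogis(prop)
    theta0 <- cummax(theta0 + (seq_len(K - 1) - 1) * 1e-4)  # strict order
    if (any(diff(theta0) <= 0)) theta0 <- seq(-1, 1, length.out = K - 1)
    start <- c(.theta_to_gamma(theta0), rep(0, p))
  }
  opt <- optim(start, .pom_nll, .pom_grad, X = X, y = y, w = w, K = K,
               method = "BFGS",
               control = list(maxit = max_iter, reltol = 1e-14))
  # polish + convergence check on the gradient norm
  g <- .pom_grad(opt$par, X, y, w, K)
  if (max(abs(g)) > tol) {
    opt2 <- optim(opt$par, .pom_nll, .pom_grad, X = X, y = y, w = w, K = K,
                  method = "BFGS",
                  control = list(maxit = max_iter, reltol = 1e-16))
    if (opt2$value <= opt$value) opt <- opt2
    g <- .pom_grad(opt$par, X, y, w, K)
  }
  theta <- .gamma_to_theta(opt$par[seq_len(K - 1)])
  beta <- opt$par[K - 1 + seq_len(p)]
  # gradient of the summed likelihood scales with the sample size
  converged <- max(abs(g)) < max(tol, 1e-5, 1e-7 * n_total) &&
    opt$value < 1e9
  degenerate <- any(tabulate(y, K) == 0)
  vc <- NULL
  if (hessian && converged) {
    H <- try(optimHess(c(theta, beta), .pom_nll_direct, X = X, y = y, w = w,
                       K = K), silent = TRUE)
    if (!inherits(H, "try-error")) {
      vc <- try(solve(H), silent = TRUE)
      if (inherits(vc, "try-error")) vc <- NULL
    }
  }
  list(theta = theta, beta = beta, loglik = -opt$value, vcov = vc,
       n_obs = n_total, n_params = (K - 1) + p, converged = converged,
       degenerate = degenerate, grad_norm = max(abs(g)), K = K)
}

#' Fit a proportional-odds cumulative logit model
#'
#' Maximum-likelihood fit of the cumulative logit model
#' \deqn{\mathrm{logit}\, P(Y \le j \mid x) = \theta_j - x'\beta, \qquad
#'   j = 1, \dots, K - 1,}
#' for an ordinal response with \eqn{K = 4} ordered categories and a common
#' slope vector \eqn{\beta} (proportional odds). Under this sign convention
#' a positive coefficient shifts mass toward higher (more favourable)
#' categories. Thresholds are kept ordered by a log-increment
#' reparameterization and the likelihood is maximized by BFGS with an
#' analytic gradient; duplicated design rows are collapsed into case
#' weights, so grouped and row-expanded data give identical fits.
#'
#' @param formula model formula; the response may be an ordered factor or
#'   integer levels 1..4. An intercept is never included (the thresholds
#'   play that role).
#' @param data data frame.
#' @param weights optional non-negative case weights (e.g. cell counts).
#' @param start optional start values \code{c(gamma, beta)} on the internal
#'   scale.
#' @param tol gradient-norm convergence tolerance.
#' @param max_iter maximum BFGS iterations per round.
#' @return an object of class \code{"pom"} with components \code{theta}
#'   (thresholds), \code{beta} (slopes), \code{loglik}, \code{vcov}
#'   (inverse observed information for \code{c(theta, beta)}),
#'   \code{n_obs}, \code{n_params}, \code{converged}, \code{degenerate}
#'   (some response category unobserved), plus the call, formula, terms and
#'   contrasts needed by \code{predict}.
#' @seealso \code{\link{pom_nonprop}}, \code{\link{lrt_prop_odds}},
#'   \code{\link{predict.pom}}, \code{\link{confint.pom}}
#' @examples
#' d <- counts_to_long(esba_phase_counts(), aggregate = TRUE)
#' fit <- pom(rating ~ phase + init_rating, data = d, weights = d$weight)
#' coef(fit)
#' @export
pom <- function(formula, data, weights = NULL, start = NULL, tol = 1e-8,
                max_iter = 500L) {
  cl <- match.call()
  pd <- .pom_design(formula, data, weights)
  fit <- pom_fit_xy(pd$X, pd$y, pd$w, K = 4L, start = start, tol = tol,
                    max_iter = max_iter)
  fit$call <- cl
  fit$formula <- formula
  fit$terms <- pd$terms
  fit$xlevels <- pd$xlevels
  fit$coef_names <- colnames(pd$X)
  structure(fit, class = "pom")
}

# Shared design construction: model frame without intercept column,
# complete cases only, first-level reference dummies (default contrasts).
# Weights are handled outside model.frame (no non-standard evaluation).
.pom_design <- function(formula, data, weights = NULL) {
  tt <- stats::terms(formula, data = data)
  mf <- stats::model.frame(tt, data, na.action = stats::na.pass)
  w <- if (is.null(weights)) rep(1, nrow(mf)) else as.numeric(weights)
  if (length(w) != nrow(mf)) stop("weights length does not match data")
  if (any(w < 0, na.rm = TRUE)) stop("negative weights")
  keep <- stats::complete.cases(mf) & !is.na(w)
  mf <- mf[keep, , drop = FALSE]
  w <- w[keep]
  y <- stats::model.response(mf)
  y <- if (is.ordered(y) || is.factor(y)) as.integer(y) else as_frankl(y)
  X <- stats::model.matrix(tt, mf)
  X <- X[, colnames(X) != "(Intercept)", drop = FALSE]
  list(X = X, y = y, w = w, terms = tt, xlevels = stats::.getXlevels(tt, mf))
}

#' @export
print.pom <- function(x, digits = 4, ...) {
  cat("Proportional-odds cumulative logit model\n")
  cat("logit P(Y <= j | x) = theta_j - x'beta\n\n")
  cat("Thresholds:\n")
  print(round(setNames(x$theta, paste0(1:(x$K - 1), "|", 2:x$K)), digits))
  if (length(x$beta)) {
    cat("\nCoefficients:\n")
    print(round(setNames(x$beta, x$coef_names), digits))
  }
  cat("\nlog-likelihood:", format(x$loglik, digits = 7),
      " BIC:", format(BIC(x), digits = 7),
      " n:", x$n_obs, "\n")
  if (!x$converged) cat("WARNING: fit did not converge\n")
  if (x$degenerate)
    cat("NOTE: some response category unobserved (degenerate fit)\n")
  invisible(x)
}

#' @export
coef.pom <- function(object, ...) setNames(object$beta, object$coef_names)

#' @export
vcov.pom <- function(object, ...) {
  if (is.null(object$vcov)) stop("no covariance available (fit not converged?)")
  vc <- object$vcov
  nm <- c(paste0(1:(object$K - 1), "|", 2:object$K), object$coef_names)
  dimnames(vc) <- list(nm, nm)
  vc
}

#' @export
logLik.pom <- function(object, ...) {
  structure(object$loglik, df = object$n_params, nobs = object$n_obs,
            class = "logLik")
}

#' @export
nobs.pom <- function(object, ...) object$n_obs

#' Summary of a proportional-odds fit
#'
#' Coefficient table with standard errors from the inverse observed
#' information and two-sided Wald z-tests.
#'
#' @param object a \code{\link{pom}} fit.
#' @param ... unused.
#' @export
summary.pom <- function(object, ...) {
  vc <- vcov(object)
  se <- sqrt(diag(vc))
  est <- c(setNames(object$theta,
                    paste0(1:(object$K - 1), "|", 2:object$K)),
           coef(object))
  z <- est / se
  tab <- cbind(Estimate = est, `Std. Error` = se, `z value` = z,
               `Pr(>|z|)` = 2 * pnorm(-abs(z)))
  structure(list(coefficients = tab, loglik = object$loglik,
                 bic = BIC(object), n_obs = object$n_obs,
                 n_thresh = object$K - 1, converged = object$converged),
            class = "summary.pom")
}

#' @export
print.summary.pom <- function(x, digits = 4, ...) {
  cat("Proportional-odds cumulative logit model\n\n")
  stats::printCoefmat(x$coefficients, digits = digits, P.values = TRUE,
                      has.Pvalue = TRUE)
  cat("\nlog-likelihood:", format(x$loglik, digits = 7),
      " BIC:", format(x$bic, digits = 7), " n:", x$n_obs, "\n")
  if (!x$converged) cat("WARNING: fit did not converge\n")
  invisible(x)
}

#' Predicted category probabilities
#'
#' @param object a \code{\link{pom}} fit.
#' @param newdata data frame of covariate settings; the fitting data are
#'   reused when omitted.
#' @param type \code{"prob"} for the four category probabilities (rows on
#'   the simplex), \code{"cum"} for the three cumulative probabilities
#'   \eqn{P(Y \le j)}.
#' @param ... unused.
#' @return numeric matrix, one row per setting.
#' @export
predict.pom <- function(object, newdata = NULL, type = c("prob", "cum"),
                        ...) {
  type <- match.arg(type)
  if (!object$converged) warning("prediction from a non-converged fit")
  if (is.null(newdata)) stop("newdata required")
  tt <- stats::delete.response(object$terms)
  mf <- stats::model.frame(tt, newdata, xlev = object$xlevels)
  X <- stats::model.matrix(tt, mf)
  X <- X[, colnames(X) != "(Intercept)", drop = FALSE]
  if (!identical(colnames(X), object$coef_names))
    stop("newdata does not match the fitted design: got columns ",
         paste(colnames(X), collapse = ", "))
  eta <- drop(X %*% object$beta)
  cum <- vapply(object$theta, function(th) plogis(th - eta),
                numeric(length(eta)))
  cum <- matrix(cum, nrow = length(eta))
  if (type == "cum") {
    colnames(cum) <- paste0("P(Y<=", 1:(object$K - 1), ")")
    return(cum)
  }
  pr <- cbind(cum[, 1], cum[, -1, drop = FALSE] -
                cum[, -(object$K - 1), drop = FALSE], 1 - cum[, object$K - 1])
  colnames(pr) <- frankl_codes()
  pr
}

#' Confidence intervals for slope coefficients
#'
#' Profile-likelihood intervals (the default, matching the convention of
#' standard ordinal-regression software) invert the likelihood-ratio test:
#' the bound solves \eqn{2\{\ell(\hat\beta) - \ell_p(\beta_k)\} =
#' \chi^2_{1,level}} where \eqn{\ell_p} profiles out all other parameters.
#' \code{type = "wald"} gives \eqn{\hat\beta_k \pm z \cdot SE}.
#'
#' @param object a \code{\link{pom}} fit.
#' @param parm coefficient names (default: all slopes).
#' @param level confidence level.
#' @param type \code{"profile"} or \code{"wald"}.
#' @param ... unused.
#' @return matrix with columns \code{lower}, \code{upper}.
#' @export
confint.pom <- function(object, parm = NULL, level = 0.95,
                        type = c("profile", "wald"), ...) {
  type <- match.arg(type)
  if (!object$converged) stop("cannot compute intervals: fit not converged")
  nm <- object$coef_names
  if (is.null(parm)) parm <- nm
  idx <- match(parm, nm)
  if (anyNA(idx)) stop("unknown coefficient(s): ",
                       paste(parm[is.na(idx)], collapse = ", "))
  se <- sqrt(diag(vcov(object)))[object$K - 1 + idx]
  if (type == "wald") {
    z <- qnorm(1 - (1 - level) / 2)
    out <- cbind(lower = object$beta[idx] - z * se,
                 upper = object$beta[idx] + z * se)
    rownames(out) <- parm
    return(out)
  }
  # profile likelihood: re-optimize all other parameters at fixed beta_k
  dat <- eval(object$call$data, environment(object$formula))
  w <- eval(object$call$weights, dat, environment(object$formula))
  des <- .pom_design(object$formula, dat, w)
  crit <- qchisq(level, df = 1)
  lmax <- object$loglik
  out <- matrix(NA_real_, length(idx), 2,
                dimnames = list(parm, c("lower", "upper")))
  for (r in seq_along(idx)) {
    k <- idx[r]
    prof <- function(bk) {
      # fixed contribution of beta_k enters as an offset; re-optimize the rest
      Xk <- des$X[, -k, drop = FALSE]
      off <- des$X[, k] * bk
      nll <- function(par) {
        theta <- .gamma_to_theta(par[seq_len(object$K - 1)])
        beta <- par[object$K - 1 + seq_len(ncol(Xk))]
        eta <- off + if (ncol(Xk)) drop(Xk %*% beta) else 0
        thetaX <- c(-Inf, theta, Inf)
        p <- .logis_band(thetaX[des$y + 1L] - eta, thetaX[des$y] - eta)
        if (any(p <= 0) || any(!is.finite(p))) return(1e10)
        -sum(des$w * log(p))
      }
      st <- c(.theta_to_gamma(object$theta), object$beta[-k])
      o <- optim(st, nll, method = "BFGS",
                 control = list(maxit = 500, reltol = 1e-12))
      2 * (lmax + o$value) - crit   # > 0 outside the interval
    }
    step <- max(4 * se[r], 0.5)
    for (side in 1:2) {
      dir <- if (side == 1) -1 else 1
      lo <- object$beta[k]; hi <- object$beta[k] + dir * step
      tries <- 0
      while (prof(hi) < 0 && tries < 8) { hi <- hi + dir * step; tries <- tries + 1 }
      bound <- if (prof(hi) < 0) NA_real_ else
        uniroot(prof, sort(c(lo, hi)), tol = 1e-6)$root
      out[r, side] <- bound
    }
  }
  out
}

#' Simulate ordinal responses from a fitted model
#'
#' Draws ratings from the fitted category probabilities at each row of
#' \code{newdata} (or of a supplied design).
#'
#' @param object a \code{\link{pom}} fit.
#' @param nsim number of simulated response vectors.
#' @param seed optional integer seed.
#' @param newdata covariate settings, one simulated rating per row.
#' @param ... unused.
#' @return integer matrix, \code{nrow(newdata)} x \code{nsim}.
#' @export
simulate.pom <- function(object, nsim = 1, seed = NULL, newdata, ...) {
  if (!is.null(seed)) set.seed(seed)
  pr <- predict(object, newdata, type = "prob")
  out <- matrix(NA_integer_, nrow(pr), nsim)
  for (i in seq_len(nrow(pr)))
    out[i, ] <- sample.int(object$K, nsim, replace = TRUE, prob = pr[i, ])
  out
}

#' Grouped Pearson residuals
#'
#' Residuals \eqn{(O - E)/\sqrt{E}} over the cells of distinct covariate
#' patterns crossed with the four response categories, computed on the
#' fitting data.
#'
#' @param object a \code{\link{pom}} fit.
#' @param data the fitting data (with weights column if used).
#' @param weights optional case weights aligned with \code{data}.
#' @param ... unused.
#' @return data frame with one row per (pattern, category) cell.
#' @export
residuals.pom <- function(object, data = NULL, weights = NULL, ...) {
  if (is.null(data)) data <- eval(object$call$data,
                                  environment(object$formula))
  if (is.null(weights))
    weights <- eval(object$call$weights, data, environment(object$formula))
  g <- .pom_cells(object, data, weights)
  g$residual <- (g$observed - g$expected) / sqrt(pmax(g$expected, 1e-12))
  g
}

# observed and expected counts per covariate pattern x category
.pom_cells <- function(object, data, weights = NULL) {
  des <- .pom_design(object$formula, data, weights)
  key <- do.call(paste, c(as.data.frame(des$X), list(sep = "\r")))
  pats <- !duplicated(key)
  pid <- match(key, key[pats])
  Xp <- des$X[pats, , drop = FALSE]
  eta <- drop(Xp %*% object$beta)
  cum <- vapply(object$theta, function(th) plogis(th - eta),
                numeric(length(eta)))
  cum <- matrix(cum, nrow = length(eta))
  pr <- cbind(cum[, 1], cum[, -1, drop = FALSE] -
                cum[, -(object$K - 1), drop = FALSE], 1 - cum[, object$K - 1])
  npat <- sum(pats)
  O <- matrix(0, npat, object$K)
  for (i in seq_along(pid))
    O[pid[i], des$y[i]] <- O[pid[i], des$y[i]] + des$w[i]
  E <- pr * rowSums(O)
  data.frame(pattern = rep(seq_len(npat), object$K),
             category = rep(1:object$K, each = npat),
             observed = as.vector(O), expected = as.vector(E))
}

#' @export
BIC.pom <- function(object, ...) {
  -2 * object$loglik + object$n_params * log(object$n_obs)
}
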