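#' Stuart-Maxwell test of marginal homogeneity
#'
#' Tests whether the two marginal distributions of a paired K x K
#' contingency table (here: Frankl ratings of the same children at two
#' assessments) are equal. With \eqn{d_i = n_{i+} - n_{+i}} for the first
#' \eqn{K - 1} categories and \eqn{\hat V} the estimated covariance of
#' \eqn{d} under homogeneity (diagonal \eqn{n_{i+} + n_{+i} - 2 n_{ii}},
#' off-diagonal \eqn{-(n_{ij} + n_{ji})}), the statistic is the quadratic
#' form \eqn{d' \hat V^- d} with a Moore-Penrose generalized inverse and
#' degrees of freedom equal to \eqn{\mathrm{rank}(\hat V)}. The
#' generalized inverse handles degenerate tables (e.g. a cohort whose
#' baseline ratings are concentrated in one category, which makes
#' \eqn{\hat V} singular). No continuity correction is applied.
#'
#' For degenerate tables the choice of degrees of freedom matters:
#' \code{df = "rank"} (the default) uses the rank of \eqn{\hat V}, while
#' \code{df = "nominal"} always uses \eqn{K - 1} (the convention of some
#' implementations, which yields larger p-values when categories are
#' empty). The two agree whenever \eqn{\hat V} is non-singular.
#'
#' @param table K x K matrix of paired counts; cell \eqn{(i, j)} counts
#'   subjects rated \eqn{i} at the first and \eqn{j} at the second
#'   assessment.
#' @param df degrees-of-freedom convention, \code{"rank"} or
#'   \code{"nominal"}.
#' @return an object of class \code{"htest"} with \code{statistic},
#'   \code{parameter} (df) and \code{p.value} (1 when df = 0, i.e.
#'   the marginals are identical by construction).
#' @examples
#' tab <- transition_table(esba_phase_counts(), "cooperative", 3)
#' stuart_maxwell(tab)
#' @export
stuart_maxwell <- function(table, df = c("rank", "nominal")) {
  df <- match.arg(df)
  m <- as.matrix(table)
  K <- nrow(m)
  stopifnot(K == ncol(m), all(m >= 0), sum(m) > 0)
  d <- (rowSums(m) - colSums(m))[-K]
  V <- -(m + t(m))[-K, -K, drop = FALSE]
  diag(V) <- (rowSums(m) + colSums(m) - 2 * diag(m))[-K]
  # Moore-Penrose inverse via eigendecomposition; df = rank
  e <- eigen(V, symmetric = TRUE)
  tol <- max(dim(V)) * .Machine$double.eps * max(abs(e$values), 1)
  pos <- e$values > tol
  rank <- sum(pos)
  stat <- if (rank == 0) 0 else {
    Vinv <- e$vectors[, pos, drop = FALSE] %*%
      (t(e$vectors[, pos, drop = FALSE]) / e$values[pos])
    drop(t(d) %*% Vinv %*% d)
  }
  dof <- if (df == "rank") rank else K - 1L
  p <- if (dof == 0) 1 else pchisq(stat, dof, lower.tail = FALSE)
  structure(list(statistic = c(`chi-square` = stat),
                 parameter = c(df = dof), p.value = p,
                 method = "Stuart-Maxwell test of marginal homogeneity",
                 data.name = deparse(substitute(table))),
            class = "htest")
}
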