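#' Phase-by-category count tables
#'
#' A \code{phase_counts} object stores, for each baseline cohort
#' (uncooperative / cooperative), the number of children in each of the four
#' Frankl categories at the first visit (phase 0) and at the end of phases
#' I--III. Rows are assessment times, columns Frankl levels 1--4; each row
#' must sum to the cohort size.
#'
#' @param uncoop,coop 4x4 integer matrices (rows: first visit, phase I, II,
#'   III; columns: Frankl levels 1..4).
#' @return object of class \code{phase_counts}: a list with elements
#'   \code{uncooperative} and \code{cooperative}.
#' @export
phase_counts <- function(uncoop, coop) {
  check <- function(m, lab) {
    m <- as.matrix(m)
    storage.mode(m) <- "integer"
    if (!identical(dim(m), c(4L, 4L)))
      stop(lab, " counts must be a 4x4 matrix (4 assessments x 4 categories)")
    if (any(m < 0L)) stop(lab, " counts must be non-negative")
    n <- unique(rowSums(m))
    if (length(n) != 1L)
      stop(lab, " rows must all sum to the cohort size; got ",
           paste(rowSums(m), collapse = ", "))
    dimnames(m) <- list(c("first_visit", "phase1", "phase2", "phase3"),
                        frankl_codes())
    m
  }
  structure(list(uncooperative = check(uncoop, "uncooperative"),
                 cooperative = check(coop, "cooperative")),
            class = "phase_counts")
}

#' @export
print.phase_counts <- function(x, ...) {
  for (co in names(x)) {
    cat(co, " cohort (n = ", sum(x[[co]][1, ]), "):\n", sep = "")
    print(x[[co]])
    cat("\n")
  }
  invisible(x)
}

#' Frankl distribution of the ESBA study cohorts
#'
#' Category counts of the two study cohorts (45 initially uncooperative and
#' 40 initially cooperative children) at the first visit and at the end of
#' each ESBA phase, reconstructed from the published percentage distribution
#' by nearest-integer rounding of \code{n * percent / 100}. Every row
#' reconstructs exactly (row sums equal the cohort sizes), which the
#' constructor re-checks.
#'
#' @return a \code{\link{phase_counts}} object.
#' @examples
#' esba_phase_counts()
#' @export
esba_phase_counts <- function() {
  uncoop <- rbind(c(6, 39,  0, 0),   # 13.3%, 86.7%
                  c(5, 24, 16, 0),   # 11.1%, 53.3%, 35.6%
                  c(1, 17, 26, 1),   #  2.2%, 37.8%, 57.8%, 2.2%
                  c(0,  7, 36, 2))   #     0, 15.6%, 80.0%, 4.4%
  coop <- rbind(c(0, 0, 40, 0),
                c(0, 0, 39, 1),      # 97.5%, 2.5%
                c(0, 4, 35, 1),      # 10%, 87.5%, 2.5%
                c(0, 1, 36, 3))      # 2.5%, 90%, 7.5%
  phase_counts(uncoop, coop)
}

#' Expand phase counts to long-format pseudo-observations
#'
#' Expands a \code{\link{phase_counts}} table into one modelling row per
#' (pseudo-)child and phase, with \code{phase}, \code{init_rating} and
#' \code{rating} columns, plus a \code{weight} column of 1s (the expansion is
#' row-per-observation). Baseline (first-visit) rows are excluded unless
#' \code{include_baseline = TRUE}, in which case they appear as
#' \code{phase = 0}.
#'
#' @param counts a \code{\link{phase_counts}} object.
#' @param include_baseline logical; include first-visit rows as phase 0.
#' @param aggregate logical; if \code{TRUE} return one row per
#'   (cohort, phase, rating) cell with a \code{weight} column of cell counts
#'   instead of row-expanded observations. The two forms give identical
#'   model fits.
#' @return data frame with columns \code{init_rating}, \code{phase},
#'   \code{rating} (and \code{weight} when \code{aggregate = TRUE}).
#' @examples
#' nrow(counts_to_long(esba_phase_counts()))  # 255
#' @export
counts_to_long <- function(counts, include_baseline = FALSE,
                           aggregate = FALSE) {
  stopifnot(inherits(counts, "phase_counts"))
  phases <- if (include_baseline) 0:3 else 1:3
  cells <- expand.grid(rating = 1:4, phase = phases, init_rating = 0:1)
  cohort <- c("uncooperative", "cooperative")[cells$init_rating + 1L]
  cells$weight <- mapply(function(co, ph, r) counts[[co]][ph + 1L, r],
                         cohort, cells$phase, cells$rating)
  cells <- cells[cells$weight > 0L, c("init_rating", "phase", "rating",
                                      "weight")]
  rownames(cells) <- NULL
  if (aggregate) return(cells)
  out <- cells[rep(seq_len(nrow(cells)), cells$weight),
               c("init_rating", "phase", "rating")]
  rownames(out) <- NULL
  out
}

#' Mean Frankl score per assessment
#'
#' Assigns the numerical score 1--4 to the four Frankl categories and
#' returns the cohort mean at the first visit and at the end of each phase.
#'
#' @param counts a \code{\link{phase_counts}} object.
#' @param cohort \code{"uncooperative"} or \code{"cooperative"}.
#' @return named numeric vector of length 4 (first visit, phases I--III).
#' @examples
#' round(mean_frankl_score(esba_phase_counts(), "uncooperative"), 1)
#' @export
mean_frankl_score <- function(counts,
                              cohort = c("uncooperative", "cooperative")) {
  stopifnot(inherits(counts, "phase_counts"))
  m <- counts[[match.arg(cohort)]]
  tot <- rowSums(m)
  if (any(tot == 0)) stop("zero total count in a row")
  drop(m %*% (1:4)) / tot
}

#' Observed percentage of improved children per phase
#'
#' Applies the cohort-specific improvement definition to a count table:
#' initially uncooperative children improve by reaching positive or
#' definitely positive; initially cooperative children improve by reaching
#' definitely positive.
#'
#' @inheritParams mean_frankl_score
#' @return named numeric vector (percentages) for phases I--III.
#' @examples
#' observed_improvement_pct(esba_phase_counts(), "uncooperative")
#' @export
observed_improvement_pct <- function(counts,
                                     cohort = c("uncooperative",
                                                "cooperative")) {
  stopifnot(inherits(counts, "phase_counts"))
  cohort <- match.arg(cohort)
  m <- counts[[cohort]]
  n <- sum(m[1, ])
  lev <- if (cohort == "uncooperative") 3:4 else 4
  p <- 100 * rowSums(m[2:4, lev, drop = FALSE]) / n
  names(p) <- c("phase1", "phase2", "phase3")
  p
}

#' Baseline-to-phase transition table
#'
#' Builds the 4x4 paired contingency table (first-visit rating by
#' end-of-phase rating) consumed by \code{\link{stuart_maxwell}}. From
#' child-level records the joint table is a plain cross-tabulation. From a
#' marginal \code{\link{phase_counts}} table the joint table is determined
#' only when the cohort's baseline distribution is concentrated in a single
#' category (as for the study's cooperative cohort); otherwise an error is
#' raised, because marginals do not identify the joint distribution.
#'
#' @param x child-record data frame or a \code{\link{phase_counts}} object.
#' @param cohort for \code{phase_counts} input (or to subset records),
#'   \code{"uncooperative"} or \code{"cooperative"}.
#' @param phase integer 1..3: the later assessment.
#' @return 4x4 integer matrix, rows = first-visit rating, columns =
#'   end-of-phase rating.
#' @export
transition_table <- function(x, cohort = c("uncooperative", "cooperative"),
                             phase) {
  cohort <- match.arg(cohort)
  stopifnot(phase %in% 1:3)
  if (inherits(x, "phase_counts")) {
    base <- x[[cohort]][1, ]
    if (sum(base > 0) > 1L)
      stop("joint table undetermined: the ", cohort, " cohort has more than ",
           "one occupied baseline category, so marginal counts do not ",
           "identify the transitions; child-level data are required")
    out <- matrix(0L, 4, 4, dimnames = list(frankl_codes(), frankl_codes()))
    out[which(base > 0), ] <- x[[cohort]][phase + 1L, ]
    return(out)
  }
  stopifnot(is.data.frame(x))
  keep <- init_rating(x$frankl_t0) == (cohort == "cooperative")
  x <- x[keep, , drop = FALSE]
  later <- x[[paste0("frankl_p", phase)]]
  tab <- table(factor(as_frankl(x$frankl_t0), levels = 1:4),
               factor(as_frankl(later), levels = 1:4))
  out <- matrix(as.integer(tab), 4, 4,
                dimnames = list(frankl_codes(), frankl_codes()))
  out
}
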