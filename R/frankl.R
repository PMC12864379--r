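#' Frankl scale utilities
#'
#' The Frankl behaviour rating scale has four ordered categories:
#' 1 = definitely negative (\code{"--"}), 2 = negative (\code{"-"}),
#' 3 = positive (\code{"+"}), 4 = definitely positive (\code{"++"}).
#' \code{as_frankl()} converts integer levels or string codes to validated
#' integer levels 1--4; \code{frankl_codes()} returns the four string codes
#' in scale order; \code{frankl_factor()} returns an ordered factor suitable
#' as a model response.
#'
#' @param x integer vector in 1..4, or character vector of codes
#'   \code{"--","-","+","++"}. \code{NA} is preserved.
#' @return \code{as_frankl()}: integer vector with values in 1..4;
#'   \code{frankl_codes()}: character(4); \code{frankl_factor()}: ordered
#'   factor with levels \code{"--" < "-" < "+" < "++"}.
#' @examples
#' as_frankl(c("--", "-", "+", "++"))
#' frankl_codes()[as_frankl(3)]
#' @export
as_frankl <- function(x) {
  if (is.factor(x)) x <- as.character(x)
  if (is.character(x)) {
    out <- match(x, frankl_codes())
    bad <- !is.na(x) & is.na(out)
    if (any(bad))
      stop("invalid Frankl code(s): ", paste(unique(x[bad]), collapse = ", "))
    return(out)
  }
  x <- as.integer(x)
  bad <- !is.na(x) & (x < 1L | x > 4L)
  if (any(bad))
    stop("Frankl levels must be integers in 1..4")
  x
}

#' @rdname as_frankl
#' @export
frankl_codes <- function() c("--", "-", "+", "++")

#' @rdname as_frankl
#' @export
frankl_factor <- function(x) {
  factor(frankl_codes()[as_frankl(x)], levels = frankl_codes(), ordered = TRUE)
}

#' Baseline cooperation indicator
#'
#' Encodes the first-visit Frankl rating as the binary baseline-cohort
#' indicator: 0 for initially uncooperative children (rated definitely
#' negative or negative at the first visit) and 1 for initially cooperative
#' children (rated positive). A first-visit rating of definitely positive is
#' rejected: the study population contains no such child, and the indicator
#' is undefined for it.
#'
#' @param rating_first_visit Frankl level(s), integer 1..3 or codes.
#' @return integer vector of 0/1.
#' @examples
#' init_rating(c(1, 2, 3))  # 0 0 1
#' @export
init_rating <- function(rating_first_visit) {
  r <- as_frankl(rating_first_visit)
  if (any(r == 4L, na.rm = TRUE))
    stop("first-visit rating 'definitely positive' is not a valid baseline ",
         "category: the cohort indicator is defined only for levels 1-3")
  ifelse(r <= 2L, 0L, 1L)
}

# Column layout of a child-record data.frame.
child_record_cols <- function() {
  c("child_id", "age", "gender", "nationality", "natural_birth",
    "vaccination", "medication", "prev_anesthesia", "plaque", "gingival",
    "dmft", "frankl_t0", "frankl_p1", "frankl_p2", "frankl_p3")
}

#' Expand child records to one modelling row per phase
#'
#' Converts a child-level data frame (one row per child, with a first-visit
#' rating and end-of-phase ratings for phases I--III) into the long format
#' used for modelling: one row per child and phase, carrying the phase
#' number, the baseline cooperation indicator \code{init_rating}, the
#' baseline covariates, and the end-of-phase Frankl \code{rating}. The
#' first-visit rating enters only through \code{init_rating}; no phase-0 row
#' is emitted.
#'
#' @param records data frame with at least \code{child_id},
#'   \code{frankl_t0}, \code{frankl_p1}, \code{frankl_p2}, \code{frankl_p3};
#'   any other columns are carried along as covariates.
#' @return data frame with columns \code{child_id}, \code{phase} (1..3),
#'   \code{init_rating}, the covariates, and \code{rating}; \code{3 *
#'   nrow(records)} rows.
#' @examples
#' rec <- data.frame(child_id = "c1", frankl_t0 = 2,
#'                   frankl_p1 = 2, frankl_p2 = 3, frankl_p3 = 3)
#' children_to_long(rec)
#' @export
children_to_long <- function(records) {
  stopifnot(is.data.frame(records))
  need <- c("child_id", "frankl_t0", "frankl_p1", "frankl_p2", "frankl_p3")
  miss <- setdiff(need, names(records))
  if (length(miss))
    stop("records lack column(s): ", paste(miss, collapse = ", "))
  covars <- setdiff(names(records), need)
  if (nrow(records) == 0L) {
    out <- data.frame(child_id = character(), phase = integer(),
                      init_rating = integer())
    for (v in covars) out[[v]] <- records[[v]][0]
    out$rating <- integer()
    return(out)
  }
  phase_cols <- c("frankl_p1", "frankl_p2", "frankl_p3")
  for (k in 1:3) {
    bad <- is.na(records[[phase_cols[k]]])
    if (any(bad))
      stop("missing phase ", k, " rating for child(ren): ",
           paste(records$child_id[bad], collapse = ", "))
  }
  n <- nrow(records)
  idx <- rep(seq_len(n), each = 3L)
  out <- data.frame(child_id = records$child_id[idx],
                    phase = rep(1:3, times = n),
                    init_rating = init_rating(records$frankl_t0)[idx])
  for (v in covars) out[[v]] <- records[[v]][idx]
  out$rating <- as_frankl(as.vector(rbind(records$frankl_p1,
                                          records$frankl_p2,
                                          records$frankl_p3)))
  rownames(out) <- NULL
  out
}

#' Read and write child-record tables
#'
#' Plain-CSV input/output for child-level records. Frankl columns accept
#' either integer levels 1..4 or the string codes \code{"--","-","+","++"};
#' they are stored internally as integers.
#'
#' @param path file path of a CSV with one row per child.
#' @param x child-record data frame.
#' @return \code{read_child_records()}: validated data frame.
#' @export
read_child_records <- function(path) {
  d <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("child_id", "frankl_t0", "frankl_p1", "frankl_p2", "frankl_p3")
  miss <- setdiff(need, names(d))
  if (length(miss))
    stop("file ", path, " lacks column(s): ", paste(miss, collapse = ", "))
  for (v in grep("^frankl_", names(d), value = TRUE))
    d[[v]] <- as_frankl(d[[v]])
  if (any(d$frankl_t0 == 4L, na.rm = TRUE))
    stop("first-visit rating 4 (definitely positive) found; the baseline ",
         "cohort indicator is undefined for it")
  d
}

#' @rdname read_child_records
#' @export
write_child_records <- function(x, path) {
  utils::write.csv(x, path, row.names = FALSE, quote = FALSE, na = "")
  invisible(path)
}
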