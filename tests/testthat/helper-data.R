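# Shared fixtures, built in code.

fixture_long <- function(aggregate = FALSE) {
  counts_to_long(esba_phase_counts(), aggregate = aggregate)
}

fixture_fit <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) {
      d <- fixture_long()
      cache <<- pom(rating ~ phase + init_rating, data = d)
    }
    cache
  }
})

# independent negative log-likelihood used by oracle checks: direct sum of
# log category probabilities, no shared code with the package internals
oracle_nll <- function(theta, beta, X, y, w = rep(1, length(y))) {
  if (is.unsorted(theta, strictly = TRUE)) return(Inf)
  eta <- drop(as.matrix(X) %*% beta)
  cum <- cbind(0, sapply(theta, function(t) 1 / (1 + exp(-(t - eta)))), 1)
  pr <- cum[cbind(seq_along(y), y + 1L)] - cum[cbind(seq_along(y), y)]
  if (any(pr <= 0)) return(Inf)
  -sum(w * log(pr))
}

# a small random paired-rating table
random_paired_table <- function(n = 50) {
  matrix(tabulate(sample(16, n, replace = TRUE), 16), 4, 4)
}
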