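# Independent brute-force oracles and small fixture builders.

# naive step-up count: enumerate every r in 0..m and take the largest one
# whose predicate p_(r) <= delta[r] holds (p_(0) = 0 always holds)
brute_force_step_up <- function(p, delta) {
  ps <- sort(p)
  best <- 0L
  for (r in seq_along(ps)) {
    if (ps[r] <= delta[r]) best <- r
  }
  best
}

# naive step-down count: walk the sorted p-values until the first failure
brute_force_step_down <- function(p, delta) {
  ps <- sort(p)
  r <- 0L
  for (i in seq_along(ps)) {
    if (ps[i] > delta[i]) break
    r <- i
  }
  r
}

random_family <- function(m, mix = TRUE) {
  p <- stats::runif(m)
  if (mix) {
    k <- sample(0:m, 1L)
    if (k > 0) p[seq_len(k)] <- stats::rbeta(k, 0.3, 4)
  }
  pvalue_family(p)
}

# Chinese restaurant process: number of occupied tables after m seatings
crp_clusters <- function(mass, m) {
  k <- 0L
  for (i in seq_len(m)) {
    if (stats::runif(1) < mass / (mass + i - 1)) k <- k + 1L
  }
  k
}

# The 28,679 PISA p-values are distributed only in the journal data
# supplement of the original DP-MTP analysis and are not redistributed with
# this package.  Drop the extracted single-column p-value file at the path
# below to run the replication tests against the real data.
load_cds_pvalues <- function() {
  path <- testthat::test_path("cds", "pisa_pvalues.txt")
  if (!file.exists(path)) {
    stop("PISA supplement p-values not available: place the extracted ",
         "single-column p-value file at tests/testthat/cds/pisa_pvalues.txt ",
         "to run this replication", call. = FALSE)
  }
  read_pvalues(path)
}
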