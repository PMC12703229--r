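#' Cross-tabulate a testing decision against known truth
#'
#' Builds the 2x2 outcome table of a multiple testing decision: `V` false
#' discoveries, `S` true discoveries, `U` true non-discoveries, `T` false
#' non-discoveries, `R = V + S` total discoveries, and the false discovery
#' proportion `fdp = V / max(R, 1)`.
#'
#' @param decision an `mtp_decision`.
#' @param truth a [truth_labels] of matching length.
#' @return An object of class `"error_tally"`.
#' @examples
#' fam <- simulate_pvalues(100, pi0 = 0.8, effect = 3, seed = 1)
#' tally(mtp(fam, "bh"), fam$truth)
#' @export
tally <- function(decision, truth) {
  stopifnot(inherits(decision, "mtp_decision"),
            inherits(truth, "truth_labels"))
  if (decision$m != truth$m) {
    stop("decision has m = ", decision$m, " but truth has m = ", truth$m)
  }
  rej <- decision$rejected
  nul <- truth$is_true_null
  V <- sum(rej & nul)
  S <- sum(rej & !nul)
  U <- sum(!rej & nul)
  T_ <- sum(!rej & !nul)
  R <- V + S
  structure(
    list(V = V, S = S, U = U, T = T_, R = R,
         m = truth$m, m0 = truth$m0, m1 = truth$m - truth$m0,
         fdp = V / max(R, 1)),
    class = "error_tally"
  )
}

#' @export
print.error_tally <- function(x, ...) {
  cat("multiple testing outcome tally (m =", x$m, ")\n")
  cat(sprintf("  discoveries R = %d (false V = %d, true S = %d); FDP = %.3f\n",
              x$R, x$V, x$S, x$fdp))
  cat(sprintf("  non-discoveries = %d (true U = %d, false T = %d)\n",
              x$m - x$R, x$U, x$T))
  invisible(x)
}

# simulate n_reps families and apply a procedure; returns per-replicate
# V, S, R, m1.  Replicate seeds are split deterministically from the master
# seed so different procedures see identical families.
replicate_tallies <- function(procedure, n_reps, seed,
                              m, pi0 = 1, effect = 0, rho = 0) {
  set.seed(seed)
  seeds <- sample.int(.Machine$integer.max, n_reps)
  out <- matrix(0L, nrow = n_reps, ncol = 4L,
                dimnames = list(NULL, c("V", "S", "R", "m1")))
  for (i in seq_len(n_reps)) {
    fam <- simulate_pvalues(m, pi0 = pi0, effect = effect, rho = rho,
                            seed = seeds[i])
    tl <- tally(procedure(fam), fam$truth)
    out[i, ] <- c(tl$V, tl$S, tl$R, tl$m1)
  }
  out
}

#' Monte-Carlo estimate of the false discovery rate of a procedure
#'
#' Simulates `n_reps` independent p-value families with
#' [simulate_pvalues()] and averages the false discovery proportion of the
#' supplied procedure.  Replicate seeds are split deterministically from
#' the master seed, so calls with the same seed and generator settings
#' evaluate different procedures on identical families.
#'
#' @param procedure a function mapping a [pvalue_family] to an
#'   `mtp_decision`, e.g. `function(f) mtp(f, "by", 0.05)`.
#' @param n_reps number of simulated families (at least 2).
#' @param seed master integer seed.
#' @param m,pi0,effect,rho generator settings passed to
#'   [simulate_pvalues()].
#' @return A list with the estimate (`fdr_hat` / `fwer_hat` / `power_hat`),
#'   its Monte-Carlo standard error `se`, and `n_reps`.
#' @export
estimate_fdr <- function(procedure, n_reps, seed,
                         m, pi0 = 1, effect = 0, rho = 0) {
  if (n_reps < 2) stop("n_reps must be at least 2")
  tl <- replicate_tallies(procedure, n_reps, seed, m, pi0, effect, rho)
  fdp <- tl[, "V"] / pmax(tl[, "R"], 1)
  list(fdr_hat = mean(fdp), se = stats::sd(fdp) / sqrt(n_reps),
       n_reps = n_reps)
}

#' @rdname estimate_fdr
#' @export
estimate_fwer <- function(procedure, n_reps, seed,
                          m, pi0 = 1, effect = 0, rho = 0) {
  if (n_reps < 2) stop("n_reps must be at least 2")
  tl <- replicate_tallies(procedure, n_reps, seed, m, pi0, effect, rho)
  any_false <- as.numeric(tl[, "V"] >= 1)
  list(fwer_hat = mean(any_false),
       se = stats::sd(any_false) / sqrt(n_reps), n_reps = n_reps)
}

#' Compare error rates of several procedures on identical families
#'
#' Runs each named procedure over the same `n_reps` simulated families
#' (identical replicate seeds) and reports Monte-Carlo estimates of FDR,
#' FWER and power (mean `S / m1` over replicates with `m1 > 0`), each with
#' its standard error.
#'
#' @param procedures named list of functions mapping a [pvalue_family] to
#'   an `mtp_decision`.
#' @inheritParams estimate_fdr
#' @return A data frame with one row per procedure and columns
#'   `method`, `fdr_hat`, `fdr_se`, `fwer_hat`, `fwer_se`, `power_hat`,
#'   `power_se`.
#' @export
mtp_error_study <- function(procedures, n_reps, seed,
                            m, pi0 = 1, effect = 0, rho = 0) {
  stopifnot(is.list(procedures), length(procedures) >= 1,
            !is.null(names(procedures)))
  rows <- lapply(names(procedures), function(nm) {
    tl <- replicate_tallies(procedures[[nm]], n_reps, seed,
                            m, pi0, effect, rho)
    fdp <- tl[, "V"] / pmax(tl[, "R"], 1)
    fw <- as.numeric(tl[, "V"] >= 1)
    pw <- ifelse(tl[, "m1"] > 0, tl[, "S"] / pmax(tl[, "m1"], 1), NA_real_)
    pw <- pw[!is.na(pw)]
    data.frame(
      method = nm,
      fdr_hat = mean(fdp), fdr_se = stats::sd(fdp) / sqrt(n_reps),
      fwer_hat = mean(fw), fwer_se = stats::sd(fw) / sqrt(n_reps),
      power_hat = if (length(pw)) mean(pw) else NA_real_,
      power_se = if (length(pw) > 1) stats::sd(pw) / sqrt(length(pw))
                 else NA_real_
    )
  })
  do.call(rbind, rows)
}
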