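#' Draw a random measure from the Dirichlet process marginal
#'
#' One draw of `(nu(B_1), ..., nu(B_m))` from the Dirichlet distribution
#' with concentrations `mass_value * baseline$mass`, the finite-dimensional
#' marginal of the Dirichlet process `DP(mass_value * nu0)` over the integer
#' bins.  Uses the gamma representation: independent
#' `Gamma(mass_value * nu0_r, 1)` components normalised by their sum.  With
#' small mass values most concentrations are far below 1 and individual
#' components underflow to zero harmlessly; only if the *sum* underflows is
#' the draw retried, up to `max_retries` times, after which an error advises
#' a larger mass.  Uses (and advances) the current RNG state.
#'
#' @param baseline a [binned_measure], the DP baseline `nu0`.
#' @param mass_value positive DP precision (mass) parameter `M`.
#' @param max_retries bounded number of retries on total underflow.
#' @return A [binned_measure] drawn from the prior.
#' @export
sample_dirichlet_measure <- function(baseline, mass_value, max_retries = 100) {
  stopifnot(inherits(baseline, "binned_measure"))
  if (!is.finite(mass_value) || mass_value <= 0) {
    stop("mass_value must be a positive number")
  }
  conc <- mass_value * baseline$mass
  for (i in seq_len(max_retries)) {
    g <- stats::rgamma(length(conc), shape = conc, rate = 1)
    s <- sum(g)
    if (is.finite(s) && s > 0) return(new_binned_measure(g / s))
  }
  stop("all gamma components underflowed to zero after ", max_retries,
       " retries; increase the DP mass parameter")
}

#' Expected number of clusters under a Dirichlet process
#'
#' `sum_{i=1}^m M / (M + i - 1)`, the expected number of distinct values
#' among `m` draws from `DP(M nu0)` with a non-atomic baseline; useful for
#' eliciting the precision parameter `M`.  The value always lies in
#' `[max(1, M log((M+m)/M)), 1 + M log((M+m+1)/M)]`.  At `M = 1` it equals
#' the m-th harmonic number.
#'
#' @param mass_value positive DP precision parameter `M`.
#' @param m number of draws.
#' @return Expected cluster count, a number in `[1, m]`.
#' @examples
#' expected_clusters(1, 3)  # 11/6
#' @export
expected_clusters <- function(mass_value, m) {
  if (!is.finite(mass_value) || mass_value <= 0) {
    stop("mass_value must be a positive number")
  }
  if (m < 1L) stop("m must be at least 1")
  sum(mass_value / (mass_value + seq_len(m) - 1))
}

#' Dirichlet process sensitivity analysis of multiple testing procedures
#'
#' Fits the DP-MTP prior predictive: a Dirichlet process prior
#' `nu ~ DP(M nu0)` over the probability measure that generates the shape
#' function of FDR-valid step-up procedures.  Every realisation of `nu`
#' yields a threshold schedule `delta[r] = alpha * beta_nu(r) / m` with
#' `beta_nu(r) = sum_{j <= r} j * nu_j`, hence a step-up procedure that
#' controls the FDR at `alpha` under arbitrary dependence between the
#' p-values, and a discovery count `R`.  Monte-Carlo sampling of `nu`
#' (re-drawing `M` from its Exponential(1) hyperprior each draw, unless a
#' fixed mass is given) produces the prior predictive distribution of `R`
#' and, for each hypothesis, the proportion of draws in which its rank is
#' rejected — its prior predictive probability of significance.
#'
#' @param family a [pvalue_family].
#' @param alpha FDR level in `(0, 1)` (default 0.05).
#' @param n_draws number of Monte-Carlo draws of `nu` (default 1000).
#' @param mass either the string `"exponential"` (the default Exponential(1)
#'   hyperprior on `M`, re-sampled each draw) or a fixed positive number.
#' @param baseline DP baseline measure `nu0` as a [binned_measure];
#'   default [by_baseline_measure()] of the family's size, which matches
#'   the Benjamini-Yekutieli procedure in prior expectation.
#' @param seed optional integer seed for exact reproducibility.
#'
#' @return An object of class `"dpmtp"`: a list with per-draw `R_draws` and
#'   `M_draws`, per-hypothesis `sig_prob` (original input order),
#'   `mean_R`, `sd_R`, `quantiles` (0/25/50/75/100% of `R_draws`), and the
#'   call settings (`alpha`, `n_draws`, `mass`, `seed`, `m`) plus the
#'   `family` analysed.  Because the events `rank <= R` are nested,
#'   `sig_prob` is non-increasing in the p-value rank; every realised
#'   threshold is at most `alpha`, so `sig_prob` is exactly 0 for any
#'   p-value above `alpha`.  Tied p-values straddling a rejection boundary
#'   may receive different probabilities (ranking is stable by input
#'   position).
#'
#' @examples
#' fam <- simulate_pvalues(m = 200, pi0 = 0.7, effect = 3, seed = 1)
#' fit <- dpmtp(fam, n_draws = 200, seed = 2)
#' fit
#' @export
dpmtp <- function(family, alpha = 0.05, n_draws = 1000,
                  mass = "exponential", baseline = NULL, seed = NULL) {
  stopifnot(inherits(family, "pvalue_family"))
  if (alpha <= 0 || alpha >= 1) stop("alpha must lie in (0, 1)")
  if (n_draws < 1) stop("n_draws must be at least 1")
  fixed_mass <- NULL
  if (is.numeric(mass)) {
    if (length(mass) != 1L || !is.finite(mass) || mass <= 0) {
      stop("a fixed mass must be a single positive number")
    }
    fixed_mass <- mass
  } else if (!identical(mass, "exponential")) {
    stop("mass must be a positive number or \"exponential\"")
  }
  m <- family$m
  if (is.null(baseline)) baseline <- by_baseline_measure(m)
  stopifnot(inherits(baseline, "binned_measure"))
  if (baseline$m != m) stop("baseline has ", baseline$m, " bins, need ", m)
  if (!is.null(seed)) set.seed(seed)

  ps <- family$values[family$order]
  ranks <- seq_len(m)
  R_draws <- integer(n_draws)
  M_draws <- numeric(n_draws)
  for (i in seq_len(n_draws)) {
    M <- if (is.null(fixed_mass)) stats::rexp(1L) else fixed_mass
    nu <- sample_dirichlet_measure(baseline, M)
    delta <- alpha * cumsum(ranks * nu$mass) / m
    hits <- which(ps <= delta)
    R_draws[i] <- if (length(hits)) max(hits) else 0L
    M_draws[i] <- M
  }

  # sig_prob for rank r = fraction of draws with R >= r (nested events)
  le <- cumsum(tabulate(R_draws + 1L, nbins = m + 1L))  # draws with R <= r-1
  sig_rank <- (n_draws - le[ranks]) / n_draws
  sig_prob <- numeric(m)
  sig_prob[family$order] <- sig_rank

  structure(
    list(R_draws = R_draws, M_draws = M_draws, sig_prob = sig_prob,
         mean_R = mean(R_draws),
         sd_R = if (n_draws > 1) stats::sd(R_draws) else NA_real_,
         quantiles = stats::quantile(R_draws, c(0, 0.25, 0.5, 0.75, 1)),
         alpha = alpha, n_draws = n_draws,
         mass = if (is.null(fixed_mass)) "exponential" else fixed_mass,
         seed = seed, m = m, family = family),
    class = "dpmtp"
  )
}

#' @export
print.dpmtp <- function(x, ...) {
  cat("DP-MTP sensitivity analysis\n")
  cat("  m =", x$m, "hypotheses, alpha =", x$alpha, ",", x$n_draws,
      "prior draws\n")
  cat("  DP mass:",
      if (identical(x$mass, "exponential")) "Exponential(1) hyperprior"
      else paste("fixed at", x$mass), "\n")
  cat(sprintf("  discoveries R: mean %.1f, sd %.1f\n", x$mean_R, x$sd_R))
  invisible(x)
}

#' @export
summary.dpmtp <- function(object, ...) {
  structure(
    list(m = object$m, alpha = object$alpha, n_draws = object$n_draws,
         mass = object$mass, mean_R = object$mean_R, sd_R = object$sd_R,
         quantiles = object$quantiles,
         n_certain = sum(object$sig_prob == 1),
         n_possible = sum(object$sig_prob > 0)),
    class = "summary.dpmtp"
  )
}

#' @export
print.summary.dpmtp <- function(x, ...) {
  cat("DP-MTP prior predictive distribution of the discovery count\n")
  cat("  m =", x$m, ", alpha =", x$alpha, ",", x$n_draws, "draws, mass:",
      if (identical(x$mass, "exponential")) "Exponential(1)"
      else format(x$mass), "\n")
  cat(sprintf("  mean R = %.1f, sd = %.1f\n", x$mean_R, x$sd_R))
  cat("  quantiles (0/25/50/75/100%):",
      paste(format(x$quantiles), collapse = " "), "\n")
  cat("  hypotheses significant in every draw:", x$n_certain, "\n")
  cat("  hypotheses significant in at least one draw:", x$n_possible, "\n")
  invisible(x)
}

#' Per-hypothesis table of a DP-MTP fit
#'
#' @param x a `dpmtp` object.
#' @param row.names,optional,... passed through for compatibility.
#' @return A data frame with columns `label` (when present), `p`, `rank`
#'   and `sig_prob`, in original input order.
#' @export
as.data.frame.dpmtp <- function(x, row.names = NULL, optional = FALSE, ...) {
  fam <- x$family
  rank <- integer(fam$m)
  rank[fam$order] <- seq_len(fam$m)
  df <- data.frame(p = fam$values, rank = rank, sig_prob = x$sig_prob,
                   row.names = row.names)
  if (!is.null(fam$labels)) df <- cbind(label = fam$labels, df)
  df
}

#' Plot a DP-MTP fit
#'
#' Two base-graphics panels: a histogram of the prior predictive discovery
#' counts, and the per-hypothesis significance probability against the
#' p-value for p-values at most `alpha` (above `alpha` the probability is
#' identically zero).
#'
#' @param x a `dpmtp` object.
#' @param ... passed to [graphics::hist()].
#' @return `x`, invisibly.
#' @export
plot.dpmtp <- function(x, ...) {
  op <- graphics::par(mfrow = c(2, 1), mar = c(4, 4, 2, 1))
  on.exit(graphics::par(op))
  graphics::hist(x$R_draws, main = "Prior predictive discoveries",
                 xlab = expression(R[alpha]), col = "grey85", ...)
  graphics::abline(v = x$mean_R, lwd = 2)
  keep <- x$family$values <= x$alpha
  graphics::plot(x$family$values[keep], x$sig_prob[keep], pch = 16,
                 cex = 0.4, xlab = "p-value",
                 ylab = "Pr(significant)", ylim = c(0, 1),
                 main = "Prior predictive probability of significance")
  invisible(x)
}

#' Histogram bin table of the prior predictive discovery counts
#'
#' Plain-text analogue of the discovery-count histogram: bin edges and
#' counts, suitable for CSV export.
#'
#' @param x a `dpmtp` object.
#' @param breaks passed to [graphics::hist()] (default `"Sturges"`).
#' @return A data frame with columns `lower`, `upper`, `count`.
#' @export
dpmtp_histogram <- function(x, breaks = "Sturges") {
  stopifnot(inherits(x, "dpmtp"))
  h <- graphics::hist(x$R_draws, breaks = breaks, plot = FALSE)
  data.frame(lower = utils::head(h$breaks, -1L),
             upper = utils::tail(h$breaks, -1L),
             count = h$counts)
}

#' One random DP-MTP decision
#'
#' Draws a single random measure from the DP prior (with `M` drawn from the
#' Exponential(1) hyperprior unless fixed) and returns the corresponding
#' step-up decision.  This is the per-draw rejection rule underlying
#' [dpmtp()], exposed for error-rate simulation with [estimate_fdr()].
#'
#' @inheritParams dpmtp
#' @return An `mtp_decision`.
#' @export
dp_mtp_decision <- function(family, alpha = 0.05, mass = "exponential",
                            baseline = NULL, seed = NULL) {
  fit <- dpmtp(family, alpha = alpha, n_draws = 1L, mass = mass,
               baseline = baseline, seed = seed)
  new_mtp_decision(family, fit$R_draws[1L], "DP-MTP (single draw)", alpha)
}
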