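#' Gibbs sampler for the Dirichlet process precision parameter
#'
#' Samples the posterior of the DP mass (precision) parameter `M` given the
#' number `k` of distinct values among `m` draws, under a `Gamma(a, b)`
#' prior (the default `a = b = 1` is the standard Exponential(1) prior).
#' The posterior density is proportional to
#' `pi(M) * M^(k-1) * (M + m) * B(M + 1, m)`, with `B` the Beta function.
#' The sampler is the classic two-step data augmentation: given the current
#' `M`, draw an auxiliary variable `eta ~ Beta(M + 1, m)`; given `eta`,
#' draw `M` from a two-component gamma mixture with components
#' `Gamma(a + k, b - log eta)` and `Gamma(a + k - 1, b - log eta)`, the
#' first chosen with odds `(a + k - 1) / (m * (b - log eta))`.
#'
#' @param k number of distinct values, `1 <= k <= m`.
#' @param m number of draws.
#' @param a,b positive shape and rate of the gamma prior on `M`.
#' @param n_burn discarded burn-in iterations (default 10000).
#' @param n_keep retained iterations (default 10000).
#' @param seed optional integer seed.
#' @param init initial value of `M` (default 1, the prior mean).
#'
#' @return An object of class `"dp_precision"`: a list with the retained
#'   `draws`, posterior `mean`, `sd`, `quantiles` (0/25/50/75/100%), and
#'   the inputs (`k`, `m`, `a`, `b`, `n_burn`, `n_keep`, `seed`).
#'
#' @examples
#' fit <- sample_m_posterior(k = 20, m = 50, n_burn = 500, n_keep = 500,
#'                           seed = 1)
#' fit$mean
#' @export
sample_m_posterior <- function(k, m, a = 1, b = 1,
                               n_burn = 10000, n_keep = 10000,
                               seed = NULL, init = 1) {
  if (k < 1 || k > m) stop("need 1 <= k <= m")
  if (a <= 0 || b <= 0) stop("prior shape and rate must be positive")
  if (n_keep < 1) stop("n_keep must be at least 1")
  if (!is.null(seed)) set.seed(seed)

  M <- init
  draws <- numeric(n_keep)
  eps <- .Machine$double.eps
  for (i in seq_len(n_burn + n_keep)) {
    eta <- stats::rbeta(1L, M + 1, m)
    eta <- min(max(eta, eps), 1 - eps)   # keep log(eta) finite
    rate <- b - log(eta)
    odds <- (a + k - 1) / (m * rate)
    shape <- if (stats::runif(1L) < odds / (1 + odds)) a + k else a + k - 1
    M <- stats::rgamma(1L, shape = shape, rate = rate)
    if (i > n_burn) draws[i - n_burn] <- M
  }

  structure(
    list(draws = draws, mean = mean(draws), sd = stats::sd(draws),
         quantiles = stats::quantile(draws, c(0, 0.25, 0.5, 0.75, 1)),
         k = k, m = m, a = a, b = b, n_burn = n_burn, n_keep = n_keep,
         seed = seed),
    class = "dp_precision"
  )
}

#' @export
print.dp_precision <- function(x, ...) {
  cat("posterior of the DP precision M | k =", x$k, "distinct of m =", x$m,
      "\n")
  cat(sprintf("  Gamma(%g, %g) prior; %d burn-in + %d retained Gibbs draws\n",
              x$a, x$b, x$n_burn, x$n_keep))
  cat(sprintf("  mean %.2f, sd %.2f, median %.2f\n",
              x$mean, x$sd, x$quantiles[[3L]]))
  invisible(x)
}

#' @export
summary.dp_precision <- function(object, ...) {
  out <- c(mean = object$mean, sd = object$sd, object$quantiles,
           ess = ess_ar1(object$draws))
  class(out) <- "summary.dp_precision"
  out
}

#' @export
print.summary.dp_precision <- function(x, ...) {
  y <- unclass(x)
  print(round(y, 2))
  invisible(x)
}

#' @export
plot.dp_precision <- function(x, ...) {
  op <- graphics::par(mfrow = c(2, 1), mar = c(4, 4, 2, 1))
  on.exit(graphics::par(op))
  graphics::plot(x$draws, type = "l", xlab = "iteration", ylab = "M",
                 main = "Gibbs trace of M")
  graphics::hist(x$draws, main = "Posterior of M", xlab = "M",
                 col = "grey85", ...)
  invisible(x)
}

# first-order autocorrelation effective sample size
ess_ar1 <- function(draws) {
  n <- length(draws)
  if (n < 10L) return(n)
  r1 <- stats::cor(draws[-1L], draws[-n])
  if (!is.finite(r1) || r1 <= 0) return(n)
  n * (1 - r1) / (1 + r1)
}

#' Unnormalised log posterior density of the DP precision parameter
#'
#' Evaluates `log[ pi(M) * M^(k-1) * (M + m) * B(M + 1, m) ]` in log space,
#' with `pi(M)` the `Gamma(a, b)` prior density and `B(M + 1, m)` the
#' closed form of `integral_0^1 z^M (1 - z)^(m-1) dz`, computed via
#' log-gamma differences.
#'
#' @param M positive evaluation points (vectorised).
#' @inheritParams sample_m_posterior
#' @return Numeric vector of unnormalised log densities.
#' @export
m_posterior_log_density <- function(M, k, m, a = 1, b = 1) {
  if (any(M <= 0)) stop("M must be positive")
  if (k < 1 || k > m) stop("need 1 <= k <= m")
  (a - 1) * log(M) - b * M + (k - 1) * log(M) + log(M + m) + lbeta(M + 1, m)
}

#' Quadrature moments of the DP precision posterior
#'
#' Normalises [m_posterior_log_density()] by the trapezoid rule on a grid
#' and returns the posterior mean, standard deviation and median.  When no
#' grid is supplied, one is built automatically around the posterior mode
#' (located by 1-d optimisation on the log scale) spanning plus or minus
#' `span` Laplace standard deviations.  Serves as the deterministic oracle
#' for the Gibbs sampler.
#'
#' @inheritParams sample_m_posterior
#' @param grid optional increasing vector of positive evaluation points.
#' @param n_grid grid resolution for the automatic grid (default 4001).
#' @param span half-width of the automatic grid in Laplace standard
#'   deviations (default 12).
#' @return A list with `mean`, `sd`, `median`, `mode` and the `grid` used.
#' @export
m_posterior_moments <- function(k, m, a = 1, b = 1, grid = NULL,
                                n_grid = 4001, span = 12) {
  if (is.null(grid)) {
    opt <- stats::optimize(
      function(u) m_posterior_log_density(exp(u), k, m, a, b) + u,
      interval = c(log(1e-8), log(10 * m + 10)), maximum = TRUE
    )
    mode <- exp(opt$maximum)
    h <- max(1e-6, 1e-4 * mode)
    d2 <- (m_posterior_log_density(mode + h, k, m, a, b) -
             2 * m_posterior_log_density(mode, k, m, a, b) +
             m_posterior_log_density(mode - h, k, m, a, b)) / h^2
    sd0 <- if (is.finite(d2) && d2 < 0) 1 / sqrt(-d2) else mode
    grid <- seq(max(1e-10, mode - span * sd0), mode + span * sd0,
                length.out = n_grid)
  } else {
    mode <- NA_real_
    if (any(diff(grid) <= 0)) stop("grid must be strictly increasing")
  }
  ld <- m_posterior_log_density(grid, k, m, a, b)
  w <- exp(ld - max(ld))
  dg <- diff(grid)
  trap <- function(f) sum((f[-1L] + f[-length(f)]) / 2 * dg)
  z <- trap(w)
  mu <- trap(w * grid) / z
  m2 <- trap(w * grid^2) / z
  cdf <- c(0, cumsum((w[-1L] + w[-length(w)]) / 2 * dg)) / z
  med <- stats::approx(cdf, grid, xout = 0.5, ties = "ordered")$y
  list(mean = mu, sd = sqrt(max(m2 - mu^2, 0)), median = med,
       mode = mode, grid = grid)
}
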