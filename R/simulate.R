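#' Simulate an equicorrelated p-value family with known truth
#'
#' Generates `m` one-sided p-values from latent standard-normal test
#' statistics with exchangeable (equicorrelated) dependence built from a
#' single shared factor: `latent_i = sqrt(rho) * Z0 + sqrt(1 - rho) * Z_i`.
#' Each hypothesis is a true null with probability `pi0`; true-null p-values
#' are the upper-tail probabilities of the latent normal and are therefore
#' marginally uniform on `[0, 1]` for every `rho` (the calibrated boundary
#' case of super-uniformity).  For false nulls the latent statistic is
#' shifted by `+effect` before conversion, giving stochastically smaller
#' p-values.
#'
#' @param m number of hypotheses.
#' @param pi0 probability in `[0, 1]` that a hypothesis is a true null.
#' @param effect nonnegative mean shift of the latent statistic under the
#'   alternative (in standard-deviation units).
#' @param rho equicorrelation of the latent statistics, in `[0, 1)`.
#'   Negative equicorrelation is not supported.
#' @param seed optional integer seed; the same seed reproduces the family
#'   bit for bit.
#'
#' @return A [pvalue_family] whose `truth` component is a [truth_labels]
#'   object flagging the true nulls.
#'
#' @examples
#' fam <- simulate_pvalues(m = 50, pi0 = 0.8, effect = 3, rho = 0.5, seed = 1)
#' fam$truth$m0
#' @export
simulate_pvalues <- function(m, pi0 = 1, effect = 0, rho = 0, seed = NULL) {
  if (m < 1L) stop("m must be at least 1")
  if (pi0 < 0 || pi0 > 1) stop("pi0 must lie in [0, 1]")
  if (rho < 0 || rho >= 1) {
    stop("rho must lie in [0, 1); negative equicorrelation is not supported")
  }
  if (effect < 0) stop("effect must be nonnegative")
  if (!is.null(seed)) set.seed(seed)

  is_null <- stats::runif(m) < pi0
  z0 <- stats::rnorm(1L)
  latent <- sqrt(rho) * z0 + sqrt(1 - rho) * stats::rnorm(m)
  latent[!is_null] <- latent[!is_null] + effect
  p <- stats::pnorm(latent, lower.tail = FALSE)

  fam <- pvalue_family(p)
  fam$truth <- truth_labels(is_null)
  fam
}
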