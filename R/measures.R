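#' Probability measures on integer bins and their shape functions
#'
#' A binned measure puts mass `mass[r]` on the interval `(r - 1, r]` for
#' ranks `r = 1, ..., m`.  Such measures generate FDR-valid step-up
#' procedures: the shape function `beta(r) = sum_{j <= r} j * mass[j]`
#' scaled by `alpha / m` gives per-rank rejection thresholds that control
#' the false discovery rate at level `alpha` under arbitrary dependence
#' between the p-values.
#'
#' @param mass nonnegative numeric vector summing to 1 (tolerance `1e-9`).
#'
#' @return An object of class `"binned_measure"` with components `mass`
#'   and `m`.
#' @seealso [by_baseline_measure()], [shape_function()],
#'   [schedule_from_shape()]
#' @export
binned_measure <- function(mass) {
  mass <- as.numeric(mass)
  if (!length(mass)) stop("a binned measure needs at least one bin")
  if (anyNA(mass) || any(mass < 0)) stop("bin masses must be nonnegative")
  if (abs(sum(mass) - 1) > 1e-9) {
    stop("bin masses must sum to 1 (got ", format(sum(mass), digits = 12), ")")
  }
  new_binned_measure(mass)
}

# internal fast path: skips validation (used per Monte-Carlo draw)
new_binned_measure <- function(mass) {
  structure(list(mass = mass, m = length(mass)), class = "binned_measure")
}

#' @export
print.binned_measure <- function(x, ...) {
  cat("binned probability measure on (r-1, r], r = 1..", x$m, "\n", sep = "")
  show <- utils::head(x$mass, 5L)
  cat("  mass:", paste(format(show, digits = 4), collapse = " "),
      if (x$m > 5L) "..." else "", "\n")
  invisible(x)
}

#' Benjamini-Yekutieli baseline measure
#'
#' The measure with bin masses `1/(r * H_m)`, where `H_m` is the m-th
#' harmonic number (computed by direct summation).  Its shape function is
#' linear, `beta(r) = r / H_m`, so the induced step-up schedule is exactly
#' the Benjamini-Yekutieli one.  This is the default baseline of the
#' Dirichlet process prior in [dpmtp()].
#'
#' @param m number of bins (hypotheses).
#' @return A [binned_measure].
#' @examples
#' by_baseline_measure(3)$mass  # 6/11, 3/11, 2/11
#' @export
by_baseline_measure <- function(m) {
  if (m < 1L) stop("m must be at least 1")
  r <- seq_len(m)
  new_binned_measure(1 / (r * sum(1 / r)))
}

#' Shape function of a binned measure
#'
#' `beta(r) = sum_{j <= r} j * mass[j]`, the discrete analogue of
#' `integral_0^r x dnu(x)`.  Non-decreasing with `beta(m) <= m`.
#'
#' @param nu a [binned_measure].
#' @return Numeric vector of length `nu$m`.
#' @export
shape_function <- function(nu) {
  stopifnot(inherits(nu, "binned_measure"))
  cumsum(seq_len(nu$m) * nu$mass)
}
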