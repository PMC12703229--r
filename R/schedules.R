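#' Per-rank rejection threshold schedules
#'
#' A threshold schedule assigns a rejection threshold `delta[r]` to the
#' p-value of rank `r`.  Step-up and step-down schedules must be
#' non-decreasing in the rank; single-step schedules are constant by
#' construction but are not constrained here.
#'
#' @param delta numeric vector of thresholds in `[0, 1]`, one per rank.
#' @param alpha target error level in `(0, 1)`.
#' @param kind `"step_up"`, `"step_down"` or `"single_step"`.
#' @param method identifier for printing.
#'
#' @return An object of class `"threshold_schedule"`.
#' @export
threshold_schedule <- function(delta, alpha,
                               kind = c("step_up", "step_down", "single_step"),
                               method = "custom") {
  kind <- match.arg(kind)
  delta <- as.numeric(delta)
  if (!length(delta)) stop("empty threshold schedule")
  if (anyNA(delta) || any(delta < 0 | delta > 1)) {
    stop("thresholds must lie in [0, 1]")
  }
  if (alpha <= 0 || alpha >= 1) stop("alpha must lie in (0, 1)")
  if (kind != "single_step" && any(diff(delta) < 0)) {
    stop("a ", kind, " schedule must be non-decreasing in the rank")
  }
  structure(
    list(delta = delta, alpha = alpha, kind = kind, method = method),
    class = "threshold_schedule"
  )
}

#' @export
print.threshold_schedule <- function(x, ...) {
  cat(x$kind, "threshold schedule (", x$method, "), alpha = ", x$alpha,
      ", m = ", length(x$delta), "\n", sep = "")
  invisible(x)
}

#' Step-up schedule induced by a shape function
#'
#' Converts a non-decreasing shape function `beta` into the step-up
#' schedule `delta[r] = alpha * beta[r] / m` (clipped to `[0, 1]`), the
#' threshold function that controls FDR at `alpha` under arbitrary
#' dependence for the measure generating `beta`.
#'
#' @param beta non-decreasing numeric vector, e.g. from [shape_function()].
#' @param alpha target FDR level.
#' @param method identifier for printing.
#' @return A step-up [threshold_schedule] of length `length(beta)`.
#' @export
schedule_from_shape <- function(beta, alpha, method = "shape") {
  beta <- as.numeric(beta)
  if (any(diff(beta) < 0)) stop("shape function must be non-decreasing")
  m <- length(beta)
  threshold_schedule(pmin(pmax(alpha * beta / m, 0), 1), alpha,
                     kind = "step_up", method = method)
}

# schedule builders for the named procedures -------------------------------

bh_schedule <- function(m, alpha) {
  threshold_schedule(alpha * seq_len(m) / m, alpha, "step_up", "BH")
}

by_schedule <- function(m, alpha) {
  h <- sum(1 / seq_len(m))
  threshold_schedule(alpha * seq_len(m) / (m * h), alpha, "step_up", "BY")
}

holm_schedule <- function(m, alpha) {
  threshold_schedule(alpha / (m - seq_len(m) + 1), alpha, "step_down", "Holm")
}
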