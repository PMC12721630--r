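#' Complete a Wald (estimate, CI, p) triple
#'
#' Reconstructs whichever members of a Wald-inference triple are missing from
#' the others. On the `"log"` scale (hazard ratios and other ratio measures):
#' `hr = exp((ln lo + ln hi)/2)`, `se = (ln hi - ln lo)/(2 z)`,
#' `p = 2 (1 - Phi(|ln hr| / se))`. On the `"linear"` scale (regression
#' coefficients): the estimate is the CI midpoint and `se = (hi - lo)/(2 z)`.
#'
#' @param estimate point estimate (HR on the log scale; coefficient on the
#'   linear scale), or NULL to derive it from the CI.
#' @param ci length-2 confidence bounds `(lo, hi)`, or NULL to derive from
#'   `estimate` and `se`.
#' @param se standard error (of the log-estimate on the log scale), or NULL.
#' @param scale `"log"` or `"linear"`.
#' @param conf confidence level of the interval.
#' @return list with `estimate`, `se`, `ci`, `p` (and `log_estimate` on the
#'   log scale).
#' @export
wald_complete <- function(estimate = NULL, ci = NULL, se = NULL,
                          scale = c("log", "linear"), conf = 0.95) {
  scale <- match.arg(scale)
  z <- stats::qnorm(1 - (1 - conf) / 2)
  if (!is.null(ci)) {
    if (length(ci) != 2 || ci[1] >= ci[2])
      stop("ci must be (lo, hi) with lo < hi")
    if (scale == "log" && any(ci <= 0))
      stop("log-scale ci bounds must be positive")
  }
  if (scale == "log") {
    if (is.null(estimate) && is.null(ci)) stop("need an estimate or a ci")
    if (is.null(estimate)) estimate <- exp((log(ci[1]) + log(ci[2])) / 2)
    if (estimate <= 0) stop("log-scale estimate must be positive")
    le <- log(estimate)
    if (is.null(se)) {
      if (is.null(ci)) stop("need a ci or an se")
      se <- (log(ci[2]) - log(ci[1])) / (2 * z)
    }
    if (is.null(ci)) ci <- exp(c(le - z * se, le + z * se))
    p <- if (se > 0) 2 * (1 - stats::pnorm(abs(le) / se)) else 0
    return(list(estimate = estimate, log_estimate = le, se = se,
                ci = ci, p = p))
  }
  if (is.null(estimate)) {
    if (is.null(ci)) stop("need an estimate or a ci")
    estimate <- (ci[1] + ci[2]) / 2
  }
  if (is.null(se)) {
    if (is.null(ci)) stop("need a ci or an se")
    se <- (ci[2] - ci[1]) / (2 * z)
  }
  if (is.null(ci)) ci <- c(estimate - z * se, estimate + z * se)
  p <- if (se > 0) 2 * (1 - stats::pnorm(abs(estimate) / se)) else 0
  list(estimate = estimate, se = se, ci = ci, p = p)
}

#' Hazard ratio implied by its confidence interval
#'
#' Geometric midpoint of a ratio-scale Wald interval, the standard way to
#' recover a printed hazard ratio from its CI bounds.
#'
#' @param lo,hi positive CI bounds, `lo < hi`.
#' @return the implied hazard ratio.
#' @export
hr_from_ci <- function(lo, hi) {
  wald_complete(ci = c(lo, hi), scale = "log")$estimate
}

#' Two-sample power for a mean difference (normal approximation)
#'
#' Two-sided power `Phi(|delta|/SE - z) + Phi(-|delta|/SE - z)` with
#' `SE = sd * sqrt(1/n1 + 1/n2)` and `z` the upper `alpha/2` normal quantile.
#' Supports unequal allocation (e.g. bottom tertile vs the upper two).
#'
#' @param delta mean difference to detect (e.g. in log-RLU).
#' @param sd common SD.
#' @param n1,n2 group sizes (>= 2).
#' @param alpha two-sided level.
#' @return list of class `power_spec`: `delta`, `sd`, `n1`, `n2`, `alpha`,
#'   `power`.
#' @export
power_two_sample <- function(delta, sd, n1, n2, alpha = 0.05) {
  if (sd <= 0) stop("sd must be positive")
  if (n1 < 2 || n2 < 2) stop("group sizes must be at least 2")
  if (alpha <= 0 || alpha >= 1) stop("alpha must lie in (0, 1)")
  z <- stats::qnorm(1 - alpha / 2)
  ncp <- abs(delta) / (sd * sqrt(1 / n1 + 1 / n2))
  power <- stats::pnorm(ncp - z) + stats::pnorm(-ncp - z)
  structure(list(delta = delta, sd = sd, n1 = n1, n2 = n2, alpha = alpha,
                 power = power), class = "power_spec")
}

#' @export
print.power_spec <- function(x, ...) {
  cat(sprintf("power = %.3f to detect delta = %g (sd %g) with n = %d + %d at two-sided alpha = %g\n",
              x$power, x$delta, x$sd, x$n1, x$n2, x$alpha))
  invisible(x)
}
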