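#' Validate the genetic instrument
#'
#' Checks the three instrumental-variable assumptions for the one-sample
#' cis-MR design. Relevance: F-statistic of the first-stage regression of
#' log-Lp(a) on the instrument (single-predictor form
#' `F = (n - 2) R2 / (1 - R2)`; F > 10 is the conventional weak-instrument
#' threshold; an exact fit is reported as the +Inf sentinel). Independence:
#' each supplied confounder is compared across the instrument groups with
#' [two_group_test()]. Exclusion restriction: addressed by the cis design
#' itself, with the MR-Egger intercept p-value (from [mr_egger()]) attached
#' when available.
#'
#' @param instrument numeric instrument (0/1 reference vs alternative group,
#'   or the continuous per-SD score).
#' @param lpa plasma Lp(a), mg/dL.
#' @param confounders optional data.frame of confounders to screen.
#' @param egger_fit optional `egger_fit` object supplying the intercept test.
#' @return list of class `instrument_check`: `f_statistic`, `relevance_pass`,
#'   `r2`, `n`, `independence_table`, `egger_intercept_p`.
#' @export
validate_instrument <- function(instrument, lpa, confounders = NULL,
                                egger_fit = NULL) {
  keep <- !is.na(instrument) & !is.na(lpa)
  g <- as.numeric(instrument[keep]); y <- log(lpa[keep])
  n <- length(g)
  if (n < 3) stop("instrument validation needs at least 3 subjects")
  if (stats::var(g) == 0) stop("empty instrument group: instrument is constant")
  r <- sum((g - mean(g)) * (y - mean(y))) /
    sqrt(sum((g - mean(g))^2) * sum((y - mean(y))^2))
  r2 <- r^2
  f <- if (r2 >= 1) Inf else (n - 2) * r2 / (1 - r2)
  indep <- NULL
  if (!is.null(confounders)) {
    cf <- as.data.frame(confounders)[keep, , drop = FALSE]
    is_bin <- length(unique(g)) == 2
    if (!is_bin) stop("independence screen requires a dichotomous instrument")
    lv <- sort(unique(g))
    indep <- do.call(rbind, lapply(names(cf), function(nm) {
      tr <- tryCatch(two_group_test(cf[[nm]][g == lv[1]], cf[[nm]][g == lv[2]]),
                     error = function(e) NULL)
      if (is.null(tr)) return(NULL)
      data.frame(confounder = nm, method = tr$method,
                 statistic = tr$statistic, p = tr$p)
    }))
  }
  structure(list(f_statistic = f, relevance_pass = f > 10, r2 = r2, n = n,
                 independence_table = indep,
                 egger_intercept_p = if (!is.null(egger_fit)) egger_fit$intercept_p else NA_real_),
            class = "instrument_check")
}

#' @export
print.instrument_check <- function(x, ...) {
  cat(sprintf("first-stage F = %.3f (R2 = %.4f, n = %d): relevance %s\n",
              x$f_statistic, x$r2, x$n,
              if (x$relevance_pass) "PASS (F > 10)" else "FAIL (weak instrument)"))
  if (!is.na(x$egger_intercept_p))
    cat(sprintf("MR-Egger intercept p = %.3f\n", x$egger_intercept_p))
  if (!is.null(x$independence_table)) {
    cat("independence screen:\n")
    print(transform(x$independence_table, p = signif(p, 3)))
  }
  invisible(x)
}

#' One-sample Mendelian randomization estimate
#'
#' Causal effect of the exposure on the outcome per unit of exposure.
#' `grs_contrast` is the Wald ratio of group contrasts:
#' (mean outcome in the alternative group - reference) / (mean exposure
#' difference). `two_stage` regresses the outcome on the first-stage fitted
#' exposure (two-stage least squares); with a binary instrument and no
#' covariates the two coincide exactly. Standard errors and percentile
#' confidence intervals come from a seeded nonparametric bootstrap over
#' subjects.
#'
#' @param instrument numeric instrument vector (binary group or continuous
#'   score).
#' @param exposure exposure (plasma Lp(a), mg/dL).
#' @param outcome outcome vector.
#' @param method `"grs_contrast"` or `"two_stage"`.
#' @param boot_reps bootstrap replicates (0 skips the bootstrap).
#' @param seed bootstrap seed.
#' @param conf confidence level.
#' @return list of class `mr_estimate`: `method`, `estimate` (outcome units
#'   per unit exposure), `se`, `ci`, `p`, `n`, `boot_reps`.
#' @export
mr_estimate <- function(instrument, exposure, outcome,
                        method = c("grs_contrast", "two_stage"),
                        boot_reps = 2000L, seed = 1L, conf = 0.95) {
  method <- match.arg(method)
  keep <- !is.na(instrument) & !is.na(exposure) & !is.na(outcome)
  g <- as.numeric(instrument[keep]); x <- exposure[keep]; y <- outcome[keep]
  n <- length(g)
  if (stats::var(g) == 0) stop("instrument is constant")
  point <- function(g, x, y) {
    if (method == "grs_contrast") {
      lv <- sort(unique(g))
      if (length(lv) != 2) stop("grs_contrast requires a dichotomous instrument")
      dx <- mean(x[g == lv[2]]) - mean(x[g == lv[1]])
      dy <- mean(y[g == lv[2]]) - mean(y[g == lv[1]])
      if (abs(dx) < 1e-10 * (stats::sd(x) + 1e-300))
        stop("weak instrument: exposure group difference is ~0, ratio unstable")
      dy / dx
    } else {
      fit1 <- stats::coef(stats::lm.fit(cbind(1, g), x))
      xhat <- fit1[1] + fit1[2] * g
      if (stats::var(xhat) < 1e-20)
        stop("weak instrument: first-stage fitted exposure is constant")
      sum((xhat - mean(xhat)) * (y - mean(y))) / sum((xhat - mean(xhat))^2)
    }
  }
  est <- point(g, x, y)
  se <- NA_real_; ci <- c(NA_real_, NA_real_); p <- NA_real_
  if (boot_reps > 0) {
    set.seed(seed)
    bs <- vapply(seq_len(boot_reps), function(i) {
      idx <- sample.int(n, n, replace = TRUE)
      tryCatch(point(g[idx], x[idx], y[idx]), error = function(e) NA_real_)
    }, numeric(1))
    se <- stats::sd(bs, na.rm = TRUE)
    a <- (1 - conf) / 2
    ci <- unname(stats::quantile(bs, c(a, 1 - a), na.rm = TRUE))
    p <- if (se > 0) 2 * stats::pnorm(-abs(est) / se) else NA_real_
  }
  structure(list(method = method, estimate = est, se = se, ci = ci, p = p,
                 n = n, boot_reps = boot_reps), class = "mr_estimate")
}

#' @export
print.mr_estimate <- function(x, ...) {
  cat(sprintf("MR (%s): %.5g per unit exposure", x$method, x$estimate))
  if (!is.na(x$se))
    cat(sprintf(" [%.5g, %.5g], se %.3g, p %.3g (%d bootstrap reps)",
                x$ci[1], x$ci[2], x$se, x$p, x$boot_reps))
  cat("\n")
  invisible(x)
}

#' MR-Egger regression over the variant panel
#'
#' Weighted least squares of the per-variant outcome associations on the
#' per-variant exposure associations with inverse-variance weights
#' `1/se_y^2`, after orienting each variant to its exposure-increasing
#' allele. The weights are treated as relative precisions: a multiplicative
#' dispersion is estimated from the weighted residuals and inference uses the
#' t distribution on k - 2 degrees of freedom (random-effects MR-Egger); the
#' intercept is the directional-pleiotropy test. With the intercept
#' constrained to zero the slope is exactly the
#' inverse-variance-weighted (IVW) estimate. At least 3 variants are needed
#' for intercept inference. In the one-sample design the betas come from the
#' same cohort, so the fit is winner's-curse-prone; it is used here as a
#' sensitivity analysis, as in standard practice.
#'
#' @param beta_x,se_x per-variant exposure associations and SEs.
#' @param beta_y,se_y per-variant outcome associations and SEs.
#' @param intercept if FALSE, constrain the intercept to 0 (IVW).
#' @return list of class `egger_fit`: `slope`, `slope_se`, `slope_p`,
#'   `intercept`, `intercept_se`, `intercept_p`, `n_variants`, `weights`.
#' @export
mr_egger <- function(beta_x, se_x, beta_y, se_y, intercept = TRUE) {
  keep <- !is.na(beta_x) & !is.na(beta_y) & !is.na(se_y) & se_y > 0
  bx <- beta_x[keep]; by <- beta_y[keep]; sy <- se_y[keep]
  k <- length(bx)
  if (intercept && k < 3)
    stop("MR-Egger intercept needs at least 3 variants")
  if (!intercept && k < 1) stop("no variants")
  flip <- ifelse(bx < 0, -1, 1)  # orient to the exposure-increasing allele
  bx <- bx * flip; by <- by * flip
  w <- 1 / sy^2
  Xd <- if (intercept) cbind(1, bx) else cbind(bx)
  XtWX <- crossprod(Xd, w * Xd)
  XtWy <- crossprod(Xd, w * by)
  coefs <- as.numeric(solve(XtWX, XtWy))
  V <- solve(XtWX)
  # multiplicative-overdispersion WLS: the declared weights are treated as
  # relative precisions and the dispersion around the Egger line is estimated
  # from the weighted residuals, with t-inference on k - p degrees of freedom
  # (in the one-sample design the per-variant outcome SEs overstate the
  # dispersion around the line, so fixed-effect normal inference would be
  # badly mis-calibrated)
  res <- as.numeric(by - Xd %*% coefs)
  df <- k - ncol(Xd)
  wrss <- sum(w * res^2)
  if (wrss <= 1e-24 * max(1, sum(w * by^2))) wrss <- 0  # numerically exact fit
  sigma2 <- if (df > 0) wrss / df else NA_real_
  ses <- unname(sqrt(diag(V) * if (is.na(sigma2)) 1 else sigma2))
  pval <- function(est, se) {
    if (!is.finite(se) || se <= 0) return(if (abs(est) < 1e-12) 1 else 0)
    if (df > 0) 2 * stats::pt(-abs(est / se), df = df)
    else 2 * stats::pnorm(-abs(est / se))
  }
  if (intercept) {
    out <- list(slope = coefs[2], slope_se = ses[2],
                slope_p = pval(coefs[2], ses[2]),
                intercept = coefs[1], intercept_se = ses[1],
                intercept_p = pval(coefs[1], ses[1]),
                n_variants = k, dispersion = sigma2, weights = w)
  } else {
    out <- list(slope = coefs[1], slope_se = ses[1],
                slope_p = pval(coefs[1], ses[1]),
                intercept = 0, intercept_se = NA_real_,
                intercept_p = NA_real_, n_variants = k,
                dispersion = sigma2, weights = w)
  }
  structure(out, class = "egger_fit")
}

#' @export
print.egger_fit <- function(x, ...) {
  cat(sprintf("MR-Egger over %d variants: slope %.5g (se %.3g, p %.3g); intercept %.5g (p %.3g)\n",
              x$n_variants, x$slope, x$slope_se, x$slope_p, x$intercept,
              x$intercept_p))
  invisible(x)
}

#' Mediation of a survival effect by nested Cox models
#'
#' Fits the exposure Cox model with and without the putative mediator
#' (arterial superoxide on the log scale) over the same complete-case
#' subjects and reports both Wald triples, the attenuation of the exposure
#' log-hazard, `100 * (1 - log(hr_adj) / log(hr_unadj))` (defined only when
#' the unadjusted HR differs from 1), and the exposure-mediator Spearman
#' correlation as the collinearity context.
#'
#' @param time,event survival fields.
#' @param exposure exposure (binary group indicator or continuous).
#' @param mediator the mediator, typically `log(basal_o2)`.
#' @param covariates optional adjustment data.frame.
#' @param ties tie handling for [cox_fit()].
#' @return list of class `mediation_result`: `unadjusted`, `mediator_adjusted`
#'   (each hr/ci/p/log_hr/se), `attenuation_pct`, `exposure_mediator_rho`,
#'   `n`, `n_dropped`, `fits`.
#' @export
mediation_cox <- function(time, event, exposure, mediator, covariates = NULL,
                          ties = "efron") {
  base <- data.frame(exposure = as.numeric(exposure), mediator = mediator)
  if (!is.null(covariates)) base <- cbind(base, as.data.frame(covariates))
  keep <- stats::complete.cases(base) & !is.na(time) & !is.na(event)
  n_dropped <- sum(!keep)
  if (n_dropped > 0 && any(event[!keep] == 1, na.rm = TRUE))
    message("mediator/covariates missing for ",
            sum(event[!keep] == 1, na.rm = TRUE),
            " subjects with events; complete-case analysis")
  base <- base[keep, , drop = FALSE]
  time <- time[keep]; event <- event[keep]
  X1 <- base[, setdiff(names(base), "mediator"), drop = FALSE]
  fit1 <- cox_fit(time, event, X1, ties = ties)
  fit2 <- cox_fit(time, event, base, ties = ties)
  triple <- function(fit) {
    i <- match("exposure", names(fit$coefficients))
    list(hr = unname(fit$hrs[i]), ci = unname(fit$wald_cis[i, ]),
         p = unname(fit$wald_ps[i]), log_hr = unname(fit$coefficients[i]),
         se = unname(fit$ses[i]))
  }
  un <- triple(fit1); ad <- triple(fit2)
  att <- if (abs(un$log_hr) > 1e-12) 100 * (1 - ad$log_hr / un$log_hr) else NA_real_
  rho <- correlate(base$exposure, base$mediator, method = "spearman")
  structure(list(unadjusted = un, mediator_adjusted = ad,
                 attenuation_pct = att, exposure_mediator_rho = rho,
                 n = nrow(base), n_dropped = n_dropped,
                 fits = list(unadjusted = fit1, adjusted = fit2)),
            class = "mediation_result_cox")
}

#' @export
print.mediation_result_cox <- function(x, ...) {
  f <- function(tr) sprintf("HR %.3f [%.3f, %.3f], p = %.3g",
                            tr$hr, tr$ci[1], tr$ci[2], tr$p)
  cat("exposure effect, unadjusted:       ", f(x$unadjusted), "\n")
  cat("exposure effect, mediator-adjusted:", f(x$mediator_adjusted), "\n")
  if (!is.na(x$attenuation_pct))
    cat(sprintf("attenuation of the exposure log-HR: %.1f%%\n", x$attenuation_pct))
  cat(sprintf("exposure-mediator Spearman rho = %.3f (p = %.3g)\n",
              x$exposure_mediator_rho$statistic, x$exposure_mediator_rho$p))
  invisible(x)
}
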