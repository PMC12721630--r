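#' General linear model with standardized betas and a bootstrap fallback
#'
#' Ordinary least squares via the QR factorization, reporting raw
#' coefficients, standardized betas (coefficients of the z-scored response on
#' z-scored predictors; for a univariate model the standardized beta equals
#' the Pearson correlation), classical t-test p-values and R2. As a guard
#' against heteroscedastic residuals, Levene's test is run on the absolute
#' residual deviations across terciles of the fitted values; when it is
#' significant at 0.05 (and `bootstrap = "auto"`), percentile bootstrap
#' confidence intervals of the coefficients are computed and the fit is
#' flagged.
#'
#' @param y response vector.
#' @param X predictor matrix or data.frame (no intercept column; added
#'   internally).
#' @param bootstrap `"auto"` (Levene-triggered), `"never"` or `"always"`.
#' @param reps bootstrap replicates.
#' @param seed bootstrap seed.
#' @return list of class `linear_fit`: `coefficients`, `standardized_betas`,
#'   `ses`, `ps`, `r2`, `levene_p`, `heteroscedastic`, `bootstrap_used`,
#'   `bootstrap_reps`, `bootstrap_cis`, `perfect_fit`, `fitted`, `residuals`.
#' @export
linear_model <- function(y, X, bootstrap = c("auto", "never", "always"),
                         reps = 2000L, seed = 1L) {
  bootstrap <- match.arg(bootstrap)
  X <- as.matrix(as.data.frame(X))
  storage.mode(X) <- "double"
  if (is.null(colnames(X))) colnames(X) <- paste0("x", seq_len(ncol(X)))
  keep <- stats::complete.cases(X) & !is.na(y)
  X <- X[keep, , drop = FALSE]; y <- y[keep]
  n <- nrow(X); p <- ncol(X) + 1L
  if (n <= p) stop("linear model needs n > number of parameters")
  Xi <- cbind(`(intercept)` = 1, X)
  qr_x <- qr(Xi)
  if (qr_x$rank < p) {
    aliased <- colnames(Xi)[qr_x$pivot[(qr_x$rank + 1):p]]
    stop("rank-deficient design: aliased columns ", paste(aliased, collapse = ", "))
  }
  beta <- qr.coef(qr_x, y)
  fitted <- as.numeric(Xi %*% beta)
  res <- y - fitted
  rss <- sum(res^2)
  sigma2 <- rss / (n - p)
  xtx_inv <- chol2inv(qr.R(qr_x))
  ses <- sqrt(pmax(diag(xtx_inv), 0) * sigma2)
  perfect <- rss < 1e-12 * max(1, sum(y^2))
  ps <- if (perfect) rep(.Machine$double.xmin, p) else {
    tt <- beta / ses
    2 * stats::pt(-abs(tt), df = n - p)
  }
  tss <- sum((y - mean(y))^2)
  r2 <- if (tss > 0) 1 - rss / tss else NA_real_
  sy <- stats::sd(y)
  std_beta <- beta[-1] * apply(X, 2, stats::sd) / sy

  lev_p <- tryCatch(levene_fitted_terciles(res, fitted), error = function(e) NA_real_)
  hetero <- !is.na(lev_p) && lev_p < 0.05
  use_boot <- bootstrap == "always" || (bootstrap == "auto" && hetero)
  boot_cis <- NULL
  if (use_boot && reps > 0) {
    set.seed(seed)
    bmat <- matrix(NA_real_, reps, p)
    for (b in seq_len(reps)) {
      idx <- sample.int(n, n, replace = TRUE)
      bmat[b, ] <- tryCatch(qr.coef(qr(Xi[idx, , drop = FALSE]), y[idx]),
                            error = function(e) rep(NA_real_, p))
    }
    boot_cis <- t(apply(bmat, 2, stats::quantile,
                        probs = c(0.025, 0.975), na.rm = TRUE))
    rownames(boot_cis) <- names(beta)
  }
  structure(list(coefficients = beta, standardized_betas = std_beta,
                 ses = ses, ps = ps, r2 = r2, levene_p = lev_p,
                 heteroscedastic = hetero, bootstrap_used = use_boot,
                 bootstrap_reps = if (use_boot) reps else 0L,
                 bootstrap_cis = boot_cis, perfect_fit = perfect,
                 fitted = fitted, residuals = res, n = n),
            class = "linear_fit")
}

# Levene's test (mean-centered) of the residuals across terciles of the
# fitted values: one-way ANOVA F on |e_ij - mean_j(e)|.
levene_fitted_terciles <- function(res, fitted) {
  g <- tertile_groups(fitted)$tertile
  z <- abs(res - stats::ave(res, g))
  k <- nlevels(g); n <- length(z)
  zbar <- mean(z)
  gm <- tapply(z, g, mean)
  gn <- tapply(z, g, length)
  ssb <- sum(gn * (gm - zbar)^2)
  ssw <- sum((z - stats::ave(z, g))^2)
  if (ssw <= 0) return(NA_real_)
  f <- (ssb / (k - 1)) / (ssw / (n - k))
  stats::pf(f, k - 1, n - k, lower.tail = FALSE)
}

#' @export
print.linear_fit <- function(x, ...) {
  tab <- data.frame(coef = x$coefficients, se = x$ses, p = x$ps)
  tab$std_beta <- c(NA, x$standardized_betas)
  print(round(tab, 6))
  cat(sprintf("R2 = %.4f, n = %d%s\n", x$r2, x$n,
              if (x$bootstrap_used) sprintf(" (bootstrap CIs, %d reps)", x$bootstrap_reps) else ""))
  invisible(x)
}

#' Moderation analysis via an interaction model
#'
#' Tests whether a binary moderator changes the slope of `y` on `x` by
#' fitting `y ~ x + m + x:m (+ covariates)`. The moderation coefficient is
#' the interaction term; its p-value comes from the OLS t-test and its
#' confidence interval from a seeded percentile bootstrap.
#'
#' @param y response.
#' @param x continuous focal predictor.
#' @param m binary moderator (0/1).
#' @param covariates optional matrix/data.frame of additional adjustments.
#' @param reps bootstrap replicates for the CI.
#' @param seed bootstrap seed.
#' @param conf confidence level.
#' @return list of class `moderation_result`: `interaction_b`, `ci`, `p`,
#'   `bootstrap_reps`, `fit`.
#' @export
moderation <- function(y, x, m, covariates = NULL, reps = 2000L, seed = 1L,
                       conf = 0.95) {
  m <- as.numeric(m)
  if (!all(m %in% c(0, 1))) stop("moderator must be binary 0/1")
  if (min(table(m)) < 10) stop("each moderator stratum needs at least 10 subjects")
  X <- data.frame(x = x, m = m, `x:m` = x * m, check.names = FALSE)
  if (!is.null(covariates)) X <- cbind(X, as.data.frame(covariates))
  fit <- linear_model(y, X, bootstrap = "never")
  b <- unname(fit$coefficients["x:m"])
  p <- unname(fit$ps[which(names(fit$coefficients) == "x:m")])
  ci <- c(NA_real_, NA_real_)
  if (reps > 0) {
    set.seed(seed)
    n <- length(y)
    Xi <- cbind(1, as.matrix(X))
    keep <- stats::complete.cases(Xi) & !is.na(y)
    Xi <- Xi[keep, , drop = FALSE]; yk <- y[keep]; nk <- nrow(Xi)
    bs <- vapply(seq_len(reps), function(i) {
      idx <- sample.int(nk, nk, replace = TRUE)
      tryCatch(qr.coef(qr(Xi[idx, , drop = FALSE]), yk[idx])[4],
               error = function(e) NA_real_)
    }, numeric(1))
    a <- (1 - conf) / 2
    ci <- unname(stats::quantile(bs, c(a, 1 - a), na.rm = TRUE))
  }
  structure(list(interaction_b = b, ci = ci, p = p, bootstrap_reps = reps,
                 fit = fit), class = "moderation_result")
}

#' @export
print.moderation_result <- function(x, ...) {
  cat(sprintf("moderation: b = %.4g [%.4g, %.4g], p = %.4g (%d bootstrap reps)\n",
              x$interaction_b, x$ci[1], x$ci[2], x$p, x$bootstrap_reps))
  invisible(x)
}
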