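#' Cox proportional hazards fit by Newton-Raphson on the partial likelihood
#'
#' Maximizes the Cox partial likelihood with the Efron correction for tied
#' event times (Breslow available by flag), starting from beta = 0 with
#' step-halving. Convergence is declared when the largest absolute component
#' of the score vector falls below `tol`. Wald standard errors come from the
#' inverse observed information; hazard ratios and confidence intervals are
#' `exp(beta +/- z * se)` and p-values are two-sided normal. A diverging
#' coefficient path (|beta| > 20) is reported as non-identifiable (monotone
#' partial likelihood / complete separation); a dataset with no events is an
#' error.
#'
#' @param time follow-up times (nonnegative).
#' @param event event indicator (1 = event, 0 = censored).
#' @param X covariate matrix or data.frame.
#' @param ties `"efron"` or `"breslow"`.
#' @param tol convergence tolerance on the score.
#' @param max_iter maximum Newton iterations.
#' @param conf confidence level for the Wald intervals.
#' @return list of class `cox_fit`: `coefficients` (log-HRs), `ses`, `hrs`,
#'   `wald_cis` (HR scale), `wald_ps`, `log_partial_likelihood`,
#'   `null_log_partial_likelihood`, `score_norm`, `ties_method`, `n`,
#'   `n_events`, `iterations`, `converged`, `vcov`.
#' @export
cox_fit <- function(time, event, X, ties = c("efron", "breslow"),
                    tol = 1e-9, max_iter = 30L, conf = 0.95) {
  ties <- match.arg(ties)
  X <- as.matrix(as.data.frame(X))
  storage.mode(X) <- "double"
  if (is.null(colnames(X))) colnames(X) <- paste0("x", seq_len(ncol(X)))
  keep <- stats::complete.cases(X) & !is.na(time) & !is.na(event)
  X <- X[keep, , drop = FALSE]
  time <- time[keep]; event <- as.integer(event[keep])
  n <- length(time); p <- ncol(X)
  if (sum(event) == 0) stop("no events: Cox model cannot be fitted")
  const <- apply(X, 2, stats::var) == 0
  if (any(const))
    stop("constant covariate: ", paste(colnames(X)[const], collapse = ", "))

  ord <- order(time)
  time <- time[ord]; event <- event[ord]; X <- X[ord, , drop = FALSE]
  # risk-set boundaries: subjects are sorted ascending, risk set at an event
  # time t is every subject with time >= t
  ut <- unique(time[event == 1])
  groups <- lapply(ut, function(t0) {
    list(first = match(TRUE, time >= t0),
         deaths = which(time == t0 & event == 1L))
  })
  pl_parts <- function(beta) {
    eta <- as.numeric(X %*% beta)
    eta <- eta - max(eta)  # numerical guard; partial likelihood is invariant
    w <- exp(eta)
    wX <- w * X
    S0 <- rev(cumsum(rev(w)))
    S1 <- apply(wX, 2, function(cl) rev(cumsum(rev(cl))))
    S1 <- matrix(S1, nrow = n)
    # upper-triangle cross-product cumulants for the information matrix
    idx <- which(upper.tri(diag(p), diag = TRUE), arr.ind = TRUE)
    S2 <- vapply(seq_len(nrow(idx)), function(k) {
      rev(cumsum(rev(w * X[, idx[k, 1]] * X[, idx[k, 2]])))
    }, numeric(n))
    S2 <- matrix(S2, nrow = n)
    ll <- 0
    score <- numeric(p)
    info <- matrix(0, p, p)
    unpack <- function(v) {
      M <- matrix(0, p, p)
      M[upper.tri(M, diag = TRUE)] <- v
      M + t(M) - diag(diag(M), p)
    }
    for (g in groups) {
      D <- g$deaths; d <- length(D); fi <- g$first
      s0g <- S0[fi]; s1g <- S1[fi, ]; s2g <- unpack(S2[fi, ])
      s0d <- sum(w[D]); s1d <- colSums(wX[D, , drop = FALSE])
      s2d <- unpack(colSums(matrix(
        vapply(seq_len(nrow(idx)), function(k) w[D] * X[D, idx[k, 1]] * X[D, idx[k, 2]],
               numeric(d)), nrow = d)))
      ll <- ll + sum(eta[D])
      score <- score + colSums(X[D, , drop = FALSE])
      frac <- if (ties == "efron") (seq_len(d) - 1) / d else rep(0, d)
      for (l in seq_len(d)) {
        denom <- s0g - frac[l] * s0d
        z1 <- s1g - frac[l] * s1d
        z2 <- s2g - frac[l] * s2d
        ll <- ll - log(denom)
        score <- score - z1 / denom
        info <- info + z2 / denom - tcrossprod(z1 / denom)
      }
    }
    list(ll = ll, score = score, info = info)
  }

  beta <- rep(0, p)
  parts <- pl_parts(beta)
  ll0 <- pl_parts(rep(0, p))$ll
  converged <- FALSE
  iter <- 0L
  while (iter < max_iter) {
    iter <- iter + 1L
    if (max(abs(parts$score)) < tol) { converged <- TRUE; break }
    step <- tryCatch(solve(parts$info, parts$score), error = function(e)
      stop("singular information matrix: model not identifiable"))
    halve <- 0
    repeat {
      beta_new <- beta + step / 2^halve
      if (max(abs(beta_new)) > 20)
        stop("non-identifiable fit: diverging coefficient ",
             "(monotone partial likelihood / complete separation)")
      parts_new <- pl_parts(beta_new)
      if (parts_new$ll >= parts$ll - 1e-12 || halve >= 20) break
      halve <- halve + 1
    }
    beta <- beta_new
    parts <- parts_new
  }
  if (!converged && max(abs(parts$score)) < tol) converged <- TRUE
  vcov <- solve(parts$info)
  ses <- sqrt(pmax(diag(vcov), 0))
  z <- stats::qnorm(1 - (1 - conf) / 2)
  names(beta) <- names(ses) <- colnames(X)
  zstat <- beta / ses
  cis <- cbind(lower = exp(beta - z * ses), upper = exp(beta + z * ses))
  structure(list(coefficients = beta, ses = ses, hrs = exp(beta),
                 wald_cis = cis,
                 wald_ps = 2 * stats::pnorm(-abs(zstat)),
                 log_partial_likelihood = parts$ll,
                 null_log_partial_likelihood = ll0,
                 score_norm = max(abs(parts$score)),
                 ties_method = ties, n = n, n_events = sum(event),
                 iterations = iter, converged = converged, vcov = vcov),
            class = "cox_fit")
}

#' @export
print.cox_fit <- function(x, ...) {
  tab <- data.frame(coef = x$coefficients, HR = x$hrs,
                    lower = x$wald_cis[, 1], upper = x$wald_cis[, 2],
                    se = x$ses, p = x$wald_ps)
  print(round(tab, 4))
  cat(sprintf("n = %d, events = %d, ties = %s, logPL = %.4f (%s in %d iterations)\n",
              x$n, x$n_events, x$ties_method, x$log_partial_likelihood,
              if (x$converged) "converged" else "NOT converged", x$iterations))
  invisible(x)
}
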