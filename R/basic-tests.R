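#' Two-group comparison with automatic test selection
#'
#' Implements the two-group procedure used for cohort contrasts: each group
#' is screened for normality with the Lilliefors-corrected Kolmogorov-Smirnov
#' test at the 0.05 level; if both groups pass, an unpaired Student t test
#' (pooled variance) is used, otherwise the Mann-Whitney U test. The U test
#' uses the normal approximation with tie correction, switching to exact
#' enumeration of all group assignments when `n1 + n2 <= 12`.
#'
#' @param x,y numeric samples.
#' @param auto_select if FALSE, `method` must name the test explicitly.
#' @param method `"auto"`, `"t"` or `"mannwhitney"`.
#' @param normality_alpha level of the normality screen.
#' @return list of class `lpamr_test`: `method`, `statistic`, `p`, `n`.
#' @export
two_group_test <- function(x, y, auto_select = TRUE,
                           method = c("auto", "t", "mannwhitney"),
                           normality_alpha = 0.05) {
  method <- match.arg(method)
  x <- x[!is.na(x)]; y <- y[!is.na(y)]
  if (method == "auto" && !auto_select) stop("set method when auto_select = FALSE")
  if (method == "auto") {
    normal <- function(v) {
      if (length(v) < 5 || stats::sd(v) == 0) return(FALSE)
      nortest::lillie.test(v)$p.value > normality_alpha
    }
    method <- if (normal(x) && normal(y)) "t" else "mannwhitney"
  }
  n1 <- length(x); n2 <- length(y)
  if (method == "t") {
    if (n1 < 2 || n2 < 2) stop("t test needs at least 2 observations per group")
    sp2 <- ((n1 - 1) * stats::var(x) + (n2 - 1) * stats::var(y)) / (n1 + n2 - 2)
    if (sp2 == 0) stop("zero variance in both groups: t test undefined")
    tstat <- (mean(x) - mean(y)) / sqrt(sp2 * (1 / n1 + 1 / n2))
    p <- 2 * stats::pt(-abs(tstat), df = n1 + n2 - 2)
    return(structure(list(method = "student_t", statistic = tstat,
                          p = max(p, .Machine$double.xmin), n = c(n1, n2)),
                     class = "lpamr_test"))
  }
  if (n1 < 1 || n2 < 1) stop("Mann-Whitney needs at least 1 observation per group")
  r <- rank(c(x, y), ties.method = "average")
  U <- sum(r[seq_len(n1)]) - n1 * (n1 + 1) / 2
  m <- n1 * n2
  if (n1 + n2 <= 12) {
    # exact conditional null: enumerate every assignment of the pooled
    # (mid)ranks to group 1; two-sided by symmetry of U around m/2
    combs <- utils::combn(n1 + n2, n1)
    u_all <- apply(combs, 2, function(idx) sum(r[idx])) - n1 * (n1 + 1) / 2
    p <- mean(abs(u_all - m / 2) >= abs(U - m / 2) - 1e-9)
  } else {
    N <- n1 + n2
    tie_tab <- table(r)
    tie_corr <- sum(tie_tab^3 - tie_tab) / (N * (N - 1))
    sigma2 <- m / 12 * ((N + 1) - tie_corr)
    if (sigma2 <= 0) {
      p <- 1
    } else {
      z <- (U - m / 2) / sqrt(sigma2)
      p <- min(1, 2 * stats::pnorm(-abs(z)))
    }
  }
  structure(list(method = "mann_whitney_u", statistic = U,
                 p = max(p, .Machine$double.xmin), n = c(n1, n2)),
            class = "lpamr_test")
}

#' Pearson or Spearman correlation with a t-approximation p-value
#'
#' Spearman is computed as the Pearson coefficient of the midranks, the
#' standard rank correlation under ties.
#'
#' @param x,y numeric vectors (pairwise complete, n >= 3).
#' @param method `"pearson"` or `"spearman"`.
#' @return list of class `lpamr_test` with the coefficient as `statistic`.
#' @export
correlate <- function(x, y, method = c("pearson", "spearman")) {
  method <- match.arg(method)
  keep <- !is.na(x) & !is.na(y)
  x <- x[keep]; y <- y[keep]
  n <- length(x)
  if (n < 3) stop("correlation needs at least 3 complete pairs")
  if (method == "spearman") {
    x <- rank(x, ties.method = "average")
    y <- rank(y, ties.method = "average")
  }
  if (stats::sd(x) == 0 || stats::sd(y) == 0)
    stop("constant input: correlation undefined")
  r <- sum((x - mean(x)) * (y - mean(y))) /
    sqrt(sum((x - mean(x))^2) * sum((y - mean(y))^2))
  r <- max(-1, min(1, r))
  if (abs(r) >= 1) {
    p <- .Machine$double.xmin
  } else {
    tstat <- r * sqrt((n - 2) / (1 - r^2))
    p <- max(2 * stats::pt(-abs(tstat), df = n - 2), .Machine$double.xmin)
  }
  structure(list(method = method, statistic = r, p = p, n = n),
            class = "lpamr_test")
}

#' @export
print.lpamr_test <- function(x, ...) {
  cat(sprintf("%s: statistic = %.6g, p = %.4g, n = %s\n", x$method,
              x$statistic, x$p, paste(x$n, collapse = "/")))
  invisible(x)
}

#' Benjamini-Hochberg false discovery rate adjustment
#'
#' Step-up q-values: p-values sorted ascending are scaled by `n / rank`, a
#' running minimum is taken from the largest down, capped at 1, and the
#' result is returned in the original order. q-values are monotone in sorted
#' p order and never smaller than the raw p.
#'
#' @param pvals p-values in (0, 1].
#' @return q-values, same length and order.
#' @export
bh_fdr <- function(pvals) {
  if (length(pvals) == 0) stop("empty p-value vector")
  if (any(is.na(pvals)) || any(pvals <= 0 | pvals > 1))
    stop("p-values must lie in (0, 1]")
  n <- length(pvals)
  o <- order(pvals)
  ps <- pvals[o]
  q_sorted <- rev(cummin(rev(ps * n / seq_len(n))))
  q_sorted <- pmin(q_sorted, 1)
  q <- numeric(n)
  q[o] <- q_sorted
  q
}
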