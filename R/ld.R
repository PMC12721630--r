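#' Two-locus haplotype frequencies by EM
#'
#' Maximum-likelihood haplotype frequencies for a pair of biallelic variants
#' from unphased genotypes under Hardy-Weinberg random pairing. Only double
#' heterozygotes have latent phase; the E-step splits them between the
#' cis (AB/ab) and trans (Ab/aB) configurations in proportion to the current
#' haplotype products. Convergence when the largest absolute frequency change
#' falls below 1e-10, capped at 1000 iterations.
#'
#' Haplotypes are ordered (AB, Ab, aB, ab), A/B denoting the alternative
#' allele at each locus.
#'
#' @param genotypes a `genotype_matrix` (only the two columns in `pair` are
#'   used), or a 2-column dosage matrix.
#' @param pair the two rsids (default: the first two columns).
#' @return An `ld_pair` list: `rsid_a`, `rsid_b`, `hap_freqs`,
#'   `em_iterations`, `converged`, `loglik`, `non_identifiable`, plus the
#'   linkage statistics filled in by [ld_stats()].
#' @export
em_haplotype_freqs <- function(genotypes, pair = NULL) {
  dos <- if (inherits(genotypes, "genotype_matrix")) genotypes$dosage else genotypes
  if (is.null(pair)) pair <- colnames(dos)[1:2]
  dos <- dos[, pair, drop = FALSE]
  dos <- dos[stats::complete.cases(dos), , drop = FALSE]
  n <- nrow(dos)
  if (n < 2) stop("at least 2 subjects with complete genotypes required")
  poly <- function(d) mean(d) / 2 > 0 && mean(d) / 2 < 1
  if (!poly(dos[, 1]) || !poly(dos[, 2]))
    stop("monomorphic variant in pair (", paste(pair, collapse = ", "),
         "): haplotype frequencies undefined")
  # 3x3 genotype count table, dosage of alternative allele at each locus
  cnt <- matrix(0, 3, 3)
  for (i in 0:2) for (j in 0:2) cnt[i + 1, j + 1] <- sum(dos[, 1] == i & dos[, 2] == j)
  non_identifiable <- cnt[2, 2] == n

  # fixed haplotype contributions from phase-known genotypes
  base <- c(AB = 2 * cnt[3, 3] + cnt[3, 2] + cnt[2, 3],
            Ab = 2 * cnt[3, 1] + cnt[3, 2] + cnt[2, 1],
            aB = 2 * cnt[1, 3] + cnt[1, 2] + cnt[2, 3],
            ab = 2 * cnt[1, 1] + cnt[1, 2] + cnt[2, 1])
  ndh <- cnt[2, 2]
  p <- rep(0.25, 4)
  ll_obs <- function(p) {
    probs <- c(p[4]^2, 2 * p[4] * p[3], p[3]^2,
               2 * p[4] * p[2], 2 * p[1] * p[4] + 2 * p[2] * p[3], 2 * p[3] * p[1],
               p[2]^2, 2 * p[2] * p[1], p[1]^2)
    m <- as.numeric(t(cnt))  # row i = dosage A, traversed (0,0),(0,1),... -> t(cnt)
    keep <- m > 0
    sum(m[keep] * log(pmax(probs[keep], 1e-300)))
  }
  it <- 0L
  converged <- FALSE
  trace <- ll_obs(p)
  while (it < 1000L) {
    it <- it + 1L
    cis <- p[1] * p[4]
    trans <- p[2] * p[3]
    c_prob <- if (cis + trans > 0) cis / (cis + trans) else 0.5
    exp_cnt <- base + ndh * c(c_prob, 1 - c_prob, 1 - c_prob, c_prob)
    p_new <- exp_cnt / (2 * n)
    trace <- c(trace, ll_obs(p_new))
    if (max(abs(p_new - p)) < 1e-10) {
      p <- p_new
      converged <- TRUE
      break
    }
    p <- p_new
  }
  out <- list(rsid_a = pair[1], rsid_b = pair[2],
              hap_freqs = stats::setNames(p, c("AB", "Ab", "aB", "ab")),
              em_iterations = it, converged = converged,
              loglik = ll_obs(p), loglik_trace = trace,
              non_identifiable = non_identifiable)
  out <- c(out, ld_stats(out$hap_freqs))
  structure(out, class = "ld_pair")
}

#' Linkage disequilibrium statistics from haplotype frequencies
#'
#' `D = pAB - pA*pB`; `D' = |D| / Dmax` with `Dmax = min(pA*pb, pa*pB)` when
#' `D > 0` and `min(pA*pB, pa*pb)` when `D < 0`; `r2 = D^2 /
#' (pA*pa*pB*pb)`.
#'
#' @param hap_freqs numeric vector (AB, Ab, aB, ab) summing to 1.
#' @return list with `D`, `D_prime`, `r2`.
#' @export
ld_stats <- function(hap_freqs) {
  p <- as.numeric(hap_freqs)
  if (length(p) != 4 || abs(sum(p) - 1) > 1e-9 || any(p < -1e-12))
    stop("hap_freqs must be 4 nonnegative frequencies summing to 1")
  pA <- p[1] + p[2]; pB <- p[1] + p[3]
  pa <- 1 - pA; pb <- 1 - pB
  if (pA <= 0 || pA >= 1 || pB <= 0 || pB >= 1)
    stop("monomorphic locus: linkage statistics undefined")
  D <- p[1] - pA * pB
  Dmax <- if (D > 0) min(pA * pb, pa * pB) else min(pA * pB, pa * pb)
  D_prime <- if (abs(D) < 1e-15) 0 else abs(D) / Dmax
  r2 <- D^2 / (pA * pa * pB * pb)
  list(D = D, D_prime = D_prime, r2 = r2)
}

#' @export
print.ld_pair <- function(x, ...) {
  cat("LD pair", x$rsid_a, "x", x$rsid_b, "\n")
  cat("  hap freqs:", paste(sprintf("%s=%.4f", names(x$hap_freqs), x$hap_freqs),
                            collapse = " "), "\n")
  cat(sprintf("  D=%.4f  D'=%.4f  r2=%.4f  (EM: %d iterations, %s)\n",
              x$D, x$D_prime, x$r2, x$em_iterations,
              if (x$converged) "converged" else "not converged"))
  invisible(x)
}

#' Pairwise LD matrices for a variant panel
#'
#' Runs [em_haplotype_freqs()] for every pair and assembles a single square
#' matrix with D' in the upper triangle and r2 in the lower triangle (the
#' conventional combined display), diagonal 1.
#'
#' @param genotypes a `genotype_matrix`.
#' @return A named square matrix (attribute `layout` documents the triangles).
#' @export
ld_matrix <- function(genotypes) {
  rs <- genotypes$rsid
  m <- length(rs)
  out <- matrix(1, m, m, dimnames = list(rs, rs))
  for (i in seq_len(m - 1)) for (j in (i + 1):m) {
    lp <- em_haplotype_freqs(genotypes, c(rs[i], rs[j]))
    out[i, j] <- lp$D_prime
    out[j, i] <- lp$r2
  }
  attr(out, "layout") <- "upper: D', lower: r2"
  out
}
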