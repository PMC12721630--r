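# Independent oracles and small fixtures used across the suite. These stay
# deliberately separate from the package implementation: brute-force
# enumeration, grid search and closed-form hand solutions.

# compact config for fast simulations
quick_config <- function(n = 500, seed = 1, ...) {
  sim_config(n_subjects = n, seed = seed, ...)
}

# Cox partial log-likelihood by direct summation (Breslow/no-ties form):
# valid oracle for datasets with distinct event times.
brute_cox_loglik <- function(beta, time, event, x) {
  ll <- 0
  for (i in which(event == 1)) {
    risk <- which(time >= time[i])
    ll <- ll + beta * x[i] - log(sum(exp(beta * x[risk])))
  }
  ll
}

grid_cox_mle <- function(time, event, x, grid = seq(-5, 5, by = 1e-4)) {
  lls <- vapply(grid, brute_cox_loglik, numeric(1), time = time,
                event = event, x = x)
  grid[which.max(lls)]
}

# Two-locus observed-data log-likelihood on a 1e-5 grid over the AB
# haplotype frequency; allele frequencies are fixed at their observed values
# (any phase assignment preserves allele counts, so they are the MLE).
grid_em_oracle <- function(dos, step = 1e-5) {
  pA <- mean(dos[, 1]) / 2
  pB <- mean(dos[, 2]) / 2
  lo <- max(0, pA + pB - 1)
  hi <- min(pA, pB)
  pab_grid <- seq(lo + step, hi - step, by = step)
  cnt <- table(factor(dos[, 1], levels = 0:2), factor(dos[, 2], levels = 0:2))
  ll <- vapply(pab_grid, function(pAB) {
    pAb <- pA - pAB; paB <- pB - pAB; pab <- 1 - pAB - pAb - paB
    probs <- matrix(c(pab^2, 2 * pab * paB, paB^2,
                      2 * pab * pAb, 2 * pAB * pab + 2 * pAb * paB, 2 * paB * pAB,
                      pAb^2, 2 * pAb * pAB, pAB^2), 3, 3, byrow = TRUE)
    sum(cnt * log(pmax(probs, 1e-300)))
  }, numeric(1))
  best <- pab_grid[which.max(ll)]
  c(AB = best, Ab = pA - best, aB = pB - best, ab = 1 - pA - pB + best)
}

# BH step-up computed by hand, index by index
hand_bh <- function(p) {
  n <- length(p)
  o <- order(p)
  q <- numeric(n)
  prev <- 1
  for (i in n:1) {
    prev <- min(prev, p[o[i]] * n / i)
    q[o[i]] <- prev
  }
  pmin(q, 1)
}

# weighted least squares of y on (1, x) via the explicit normal equations
hand_wls <- function(x, y, w) {
  sw <- sum(w); swx <- sum(w * x); swy <- sum(w * y)
  swxx <- sum(w * x^2); swxy <- sum(w * x * y)
  det <- sw * swxx - swx^2
  b <- (sw * swxy - swx * swy) / det
  a <- (swy * swxx - swx * swxy) / det
  va <- swxx / det
  vb <- sw / det
  list(intercept = a, slope = b, se_intercept = sqrt(va), se_slope = sqrt(vb))
}

grs_groups01 <- function(grs) {
  ifelse(grs$group == "alternative", 1,
         ifelse(grs$group == "reference", 0, NA))
}
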