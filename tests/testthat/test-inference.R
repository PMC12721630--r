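test_that("Mann-Whitney exact p-values come from full enumeration", {
  r <- two_group_test(c(1, 2, 3), c(4, 5, 6), method = "mannwhitney")
  expect_equal(r$method, "mann_whitney_u")
  expect_equal(r$statistic, 0)
  expect_equal(r$p, 0.1)  # 2 of the 20 assignments are as extreme
  # identical samples sit exactly at the null center
  r2 <- two_group_test(c(1, 2, 3), c(1, 2, 3), method = "mannwhitney")
  expect_equal(r2$statistic, 3 * 3 / 2)
  expect_equal(r2$p, 1)
  # agreement with the exact reference implementation on tie-free samples
  set.seed(9)
  for (i in 1:20) {
    n1 <- sample(3:6, 1); n2 <- sample(3:6, 1)
    x <- rnorm(n1); y <- rnorm(n2)
    ours <- two_group_test(x, y, method = "mannwhitney")
    ref <- wilcox.test(x, y, exact = TRUE, correct = FALSE)
    expect_equal(ours$p, ref$p.value, tolerance = 1e-12)
  }
})

test_that("Student t branch matches the pooled-variance reference", {
  set.seed(1)
  x <- rnorm(40); y <- rnorm(35, 0.5)
  ours <- two_group_test(x, y, method = "t")
  ref <- t.test(x, y, var.equal = TRUE)
  expect_equal(ours$statistic, unname(ref$statistic), tolerance = 1e-12)
  expect_equal(ours$p, ref$p.value, tolerance = 1e-12)
  expect_error(two_group_test(rep(1, 5), rep(1, 5), method = "t"),
               "zero variance")
})

test_that("automatic selection picks t for normal and U for skewed data", {
  set.seed(2)
  expect_equal(two_group_test(rnorm(200), rnorm(200))$method, "student_t")
  expect_equal(two_group_test(rlnorm(200, sdlog = 1.5), rlnorm(200, sdlog = 1.5))$method,
               "mann_whitney_u")
})

test_that("correlations match hand-computed midrank results and references", {
  expect_equal(correlate(1:10, 2 * (1:10) + 1)$statistic, 1)
  x <- c(-2, -1, 0, 1, 2)
  sp <- correlate(x, exp(x), method = "spearman")
  expect_equal(sp$statistic, 1)
  expect_lt(correlate(x, exp(x), method = "pearson")$statistic, 1)
  # ties: midranks by hand
  x2 <- c(1, 2, 2, 3, 5)
  y2 <- c(2, 2, 4, 4, 9)
  rx <- c(1, 2.5, 2.5, 4, 5); ry <- c(1.5, 1.5, 3.5, 3.5, 5)
  hand <- sum((rx - mean(rx)) * (ry - mean(ry))) /
    sqrt(sum((rx - mean(rx))^2) * sum((ry - mean(ry))^2))
  got <- correlate(x2, y2, method = "spearman")
  expect_equal(got$statistic, hand, tolerance = 1e-12)
  expect_equal(got$statistic,
               unname(cor(x2, y2, method = "spearman")), tolerance = 1e-12)
  expect_error(correlate(rep(1, 5), 1:5), "constant")
})

test_that("BH adjustment equals the hand step-up and the reference", {
  expect_equal(bh_fdr(c(0.01, 0.02, 0.03, 0.04)), rep(0.04, 4))
  expect_equal(bh_fdr(0.37), 0.37)
  set.seed(3)
  for (i in 1:10) {
    p <- runif(sample(2:40, 1))
    q <- bh_fdr(p)
    expect_equal(q, hand_bh(p), tolerance = 1e-14)
    expect_equal(q, p.adjust(p, "BH"), tolerance = 1e-14)
    expect_true(all(q >= p - 1e-15))
    expect_true(all(diff(q[order(p)]) >= -1e-15))
  }
  expect_error(bh_fdr(numeric(0)), "empty")
  expect_error(bh_fdr(c(0.5, 0)), "in \\(0, 1\\]")
})

test_that("linear model reproduces the closed-form normal-equations solution", {
  # 3-point dataset solved by hand: y = a + b x
  x <- c(0, 1, 2); y <- c(1, 3, 4)
  fit <- linear_model(y, data.frame(x = x))
  expect_equal(unname(fit$coefficients), c(7 / 6, 1.5), tolerance = 1e-12)
  # univariate standardized beta equals the Pearson correlation
  set.seed(4)
  x2 <- rnorm(60); y2 <- 2 + x2 + rnorm(60)
  fit2 <- linear_model(y2, data.frame(x = x2))
  expect_equal(unname(fit2$standardized_betas),
               cor(x2, y2), tolerance = 1e-10)
  ref <- lm(y2 ~ x2)
  expect_equal(unname(fit2$coefficients), unname(coef(ref)), tolerance = 1e-10)
  expect_equal(fit2$r2, summary(ref)$r.squared, tolerance = 1e-10)
  # exact fit flagged
  fit3 <- linear_model(c(1, 2, 3, 4), data.frame(x = 1:4))
  expect_true(fit3$perfect_fit)
  expect_equal(fit3$r2, 1)
  # rank deficiency names the aliased column
  expect_error(linear_model(y2, data.frame(a = x2, b = 2 * x2)),
               "aliased.*b")
})

test_that("Levene-triggered bootstrap engages only under heteroscedasticity", {
  set.seed(5)
  n <- 400
  x <- runif(n, 0, 3)
  y_hom <- 1 + x + rnorm(n, 0, 0.5)
  y_het <- 1 + x + rnorm(n, 0, 0.2 + x)
  expect_false(linear_model(y_hom, data.frame(x = x))$bootstrap_used)
  fit_het <- linear_model(y_het, data.frame(x = x), reps = 200, seed = 7)
  expect_true(fit_het$heteroscedastic)
  expect_true(fit_het$bootstrap_used)
  ci <- fit_het$bootstrap_cis["x", ]
  expect_true(ci[1] < 1 && 1 < ci[2])
})

test_that("moderation interaction equals the hand OLS solution on a tiny design", {
  # 6 rows, moderator strata relaxed via direct linear_model call
  y <- c(1, 2, 3, 2, 4, 6)
  x <- c(0, 1, 2, 0, 1, 2)
  m <- c(0, 0, 0, 1, 1, 1)
  X <- cbind(1, x, m, x * m)
  hand <- solve(crossprod(X), crossprod(X, y))
  fit <- linear_model(y, data.frame(x = x, m = m, `x:m` = x * m,
                                    check.names = FALSE))
  expect_equal(unname(fit$coefficients), as.numeric(hand), tolerance = 1e-10)
  # moderation() itself on a larger design with known interaction
  set.seed(6)
  n <- 300
  xv <- rnorm(n); mv <- rbinom(n, 1, 0.5)
  yv <- 1 + xv + mv - 0.8 * xv * mv + rnorm(n, 0, 0.5)
  mod <- moderation(yv, xv, mv, reps = 400, seed = 11)
  expect_lt(mod$p, 0.001)
  expect_true(mod$ci[1] <= mod$interaction_b &&
                mod$interaction_b <= mod$ci[2])
  expect_lt(abs(mod$interaction_b + 0.8), 0.2)
  expect_error(moderation(yv[1:12], xv[1:12], c(rep(0, 11), 1)), "stratum")
})

test_that("Cox fit is antisymmetric, rank-invariant and matches the grid oracle", {
  # label-swapped mirror forces beta = 0
  time <- c(1, 2, 3, 4, 5, 6); event <- rep(1, 6); x <- c(1, 0, 1, 0, 1, 0)
  fit0 <- cox_fit(c(time, time), c(event, event), cbind(x = c(x, 1 - x)))
  expect_lt(abs(fit0$coefficients), 1e-8)
  # rank invariance of the partial likelihood
  set.seed(7)
  t1 <- sort(runif(30)) + (1:30) * 1e-4
  ev <- rbinom(30, 1, 0.7); ev[1] <- 1
  xx <- rnorm(30)
  f1 <- cox_fit(t1, ev, cbind(x = xx))
  f2 <- cox_fit(2 * t1, ev, cbind(x = xx))
  expect_equal(f1$coefficients, f2$coefficients, tolerance = 1e-10)
  # 4-subject dataset against the 1e-4 grid search
  fit4 <- cox_fit(c(1, 2, 3, 4), rep(1, 4), cbind(x = c(1, 0, 1, 0)))
  expect_lt(abs(fit4$coefficients - grid_cox_mle(c(1, 2, 3, 4), rep(1, 4),
                                                 c(1, 0, 1, 0))), 1e-4)
  # fit improves on the null and satisfies the score condition
  expect_gte(fit4$log_partial_likelihood, fit4$null_log_partial_likelihood)
  expect_lt(fit4$score_norm, 1e-8)
})

test_that("Efron and Breslow agree without ties and diverge with ties as in the reference", {
  skip_if_not_installed("survival")
  set.seed(8)
  t1 <- sample(seq(0.1, 10, by = 0.1), 40)  # distinct
  ev <- rbinom(40, 1, 0.6); ev[which.max(t1 == max(t1))] <- 1
  x <- cbind(a = rnorm(40), b = rbinom(40, 1, 0.4))
  fe <- cox_fit(t1, ev, x, ties = "efron")
  fb <- cox_fit(t1, ev, x, ties = "breslow")
  expect_equal(fe$coefficients, fb$coefficients, tolerance = 1e-10)
  # tied data: each flavor matches survival::coxph
  t2 <- sample(1:6, 40, replace = TRUE)
  fe2 <- cox_fit(t2, ev, x, ties = "efron")
  fb2 <- cox_fit(t2, ev, x, ties = "breslow")
  re <- survival::coxph(survival::Surv(t2, ev) ~ x, ties = "efron")
  rb <- survival::coxph(survival::Surv(t2, ev) ~ x, ties = "breslow")
  expect_equal(unname(fe2$coefficients), unname(coef(re)), tolerance = 1e-7)
  expect_equal(unname(fb2$coefficients), unname(coef(rb)), tolerance = 1e-7)
  expect_gt(max(abs(fe2$coefficients - fb2$coefficients)), 1e-8)
})

test_that("degenerate Cox inputs raise the documented errors", {
  expect_error(cox_fit(1:5, rep(0, 5), cbind(x = rnorm(5))), "no events")
  expect_error(cox_fit(1:5, c(1, 1, 0, 0, 1), cbind(x = rep(2, 5))),
               "constant covariate")
  # complete separation: the largest times all share x = 1
  tt <- 1:20; ev <- rep(1, 20); xs <- c(rep(0, 10), rep(1, 10))
  expect_error(cox_fit(tt, ev, cbind(x = xs)), "non-identifiable")
})

test_that("Wald triple completion is self-consistent and errors on bad intervals", {
  # round trip: log_hr,se -> ci -> hr recovers the inputs to 1e-12
  w1 <- wald_complete(estimate = exp(0.7), se = 0.21, scale = "log")
  w2 <- wald_complete(ci = w1$ci, scale = "log")
  expect_equal(w2$log_estimate, 0.7, tolerance = 1e-12)
  expect_equal(w2$se, 0.21, tolerance = 1e-12)
  expect_error(wald_complete(ci = c(1, 1), scale = "log"), "lo < hi")
  expect_error(wald_complete(ci = c(-1, 2), scale = "log"), "positive")
  # linear scale midpoint
  wl <- wald_complete(ci = c(-3, -1), scale = "linear")
  expect_equal(wl$estimate, -2)
  expect_equal(wl$se, 2 / (2 * qnorm(0.975)), tolerance = 1e-12)
})

test_that("two-sample power matches quadrature and behaves monotonically", {
  expect_equal(power_two_sample(0, 1, 50, 50)$power, 0.05, tolerance = 1e-10)
  # numerical-integration oracle: P(|Z + ncp| > z_crit)
  num_power <- function(delta, sd, n1, n2, alpha) {
    se <- sd * sqrt(1 / n1 + 1 / n2)
    zc <- qnorm(1 - alpha / 2)
    f <- function(z) dnorm(z) * ((z + delta / se) > zc | (z + delta / se) < -zc)
    integrate(f, -12, 12, subdivisions = 2000L, rel.tol = 1e-10)$value
  }
  got <- power_two_sample(0.1, 0.28, 50, 50)$power
  expect_equal(got, num_power(0.1, 0.28, 50, 50, 0.05), tolerance = 1e-6)
  # monotone in effect size and sample sizes; saturates at 1
  p1 <- sapply(c(0.1, 0.2, 0.4, 0.8), function(d) power_two_sample(d, 0.28, 30, 60)$power)
  expect_true(all(diff(p1) > 0))
  p2 <- sapply(c(20, 40, 80), function(n) power_two_sample(0.2, 0.28, n, 60)$power)
  expect_true(all(diff(p2) > 0))
  expect_equal(power_two_sample(100, 0.28, 30, 60)$power, 1, tolerance = 1e-12)
  expect_error(power_two_sample(0.5, 0, 30, 60), "sd")
})
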